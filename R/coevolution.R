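# Amino-acid alphabet used throughout the coevolution arm; the gap is a
# 21st state during frequency counting but is excluded from coupling norms.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_STATE <- 21L
N_STATES <- 21L

#' Set of aligned orthologs keyed by species
#'
#' One aligned amino-acid sequence per species; all sequences must share the
#' alignment length. Unknown residues are treated as gaps.
#'
#' @param seqs Named character vector (names = unique species keys).
#' @return An object of class `ortholog_set`.
#' @export
ortholog_set <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)),
            all(nzchar(names(seqs))))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("all sequences must have equal (aligned) length")
  structure(list(seqs = toupper(seqs), length = L, species = names(seqs)),
            class = "ortholog_set")
}

#' Read an ortholog set from aligned FASTA
#'
#' Headers are expected as `>SPECIES|accession`; the species key is the part
#' before the first `|` (or the whole header if none).
#'
#' @param path FASTA file of pre-aligned sequences.
#' @return An [ortholog_set()].
#' @export
read_ortholog_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  species <- sub("\\|.*$", "", sub("\\s.*$", "", names(aa)))
  seqs <- as.character(aa)
  names(seqs) <- species
  ortholog_set(seqs)
}

#' Write an ortholog set as aligned FASTA
#' @param set An [ortholog_set()].
#' @param path Output path.
#' @export
write_ortholog_fasta <- function(set, path) {
  stopifnot(inherits(set, "ortholog_set"))
  aa <- Biostrings::AAStringSet(set$seqs)
  names(aa) <- paste0(set$species, "|synthetic")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

msa_to_int <- function(seqs) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- matrix(GAP_STATE, nrow = length(chars), ncol = length(chars[[1]]))
  code <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)
  for (i in seq_along(chars)) {
    v <- code[chars[[i]]]
    v[is.na(v)] <- GAP_STATE
    m[i, ] <- v
  }
  m
}

#' Concatenate two ortholog sets by species
#'
#' Rows are the species present in both sets (sorted); protein A columns
#' precede protein B columns, with the boundary index recorded. This is the
#' concatenated MSA (cMSA) on which inter-protein couplings are scored.
#'
#' @param set_a,set_b [ortholog_set()]s.
#' @return An object of class `concatenated_msa` with `seqs`, `species`,
#'   `boundary` (= length of protein A), `len_a`, `len_b`.
#' @export
concat_by_species <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "ortholog_set"), inherits(set_b, "ortholog_set"))
  shared <- sort(intersect(set_a$species, set_b$species))
  if (length(shared) < 2) stop("fewer than 2 shared species")
  seqs <- paste0(set_a$seqs[shared], set_b$seqs[shared])
  names(seqs) <- shared
  structure(list(seqs = seqs, species = shared,
                 boundary = set_a$length,
                 len_a = set_a$length, len_b = set_b$length),
            class = "concatenated_msa")
}

# Sequence weights: 1 / (number of sequences within `id` fractional identity),
# the standard redundancy reweighting.
sequence_weights <- function(mint, id = 0.8) {
  N <- nrow(mint); L <- ncol(mint)
  X <- matrix(0, N, L * N_STATES)
  X[cbind(rep(seq_len(N), L),
          (rep(seq_len(L), each = N) - 1L) * N_STATES + as.integer(mint))] <- 1
  sim <- tcrossprod(X) / L
  1 / rowSums(sim >= id - 1e-12)
}

# Weighted single/pair frequencies with a relative pseudocount lambda
# (fraction of probability mass assigned to the uniform distribution).
frequency_counts <- function(mint, w, lambda) {
  N <- nrow(mint); L <- ncol(mint); q <- N_STATES
  X <- matrix(0, N, L * q)
  X[cbind(rep(seq_len(N), L),
          (rep(seq_len(L), each = N) - 1L) * q + as.integer(mint))] <- 1
  W <- sum(w)
  fi <- colSums(X * w) / W                       # length L*q
  fij <- crossprod(X * sqrt(w)) / W              # (L*q) x (L*q)
  fi <- (1 - lambda) * fi + lambda / q
  fij <- (1 - lambda) * fij + lambda / q^2
  # i == j blocks are diagonal by definition
  for (i in seq_len(L)) {
    ix <- ((i - 1) * q + 1):(i * q)
    blk <- diag(fi[ix], q)
    fij[ix, ix] <- blk
  }
  list(fi = fi, fij = fij, q = q, L = L, W = W)
}

# Frobenius norm of a coupling block after zero-sum gauge shift.
frob_score <- function(J) {
  Jc <- J - outer(rowMeans(J), rep(1, ncol(J))) -
    outer(rep(1, nrow(J)), colMeans(J)) + mean(J)
  sqrt(sum(Jc^2))
}

# Average-product correction on a symmetric score matrix (diagonal ignored).
apc_correct <- function(S) {
  diag(S) <- NA
  rm_ <- rowMeans(S, na.rm = TRUE)
  gm <- mean(S, na.rm = TRUE)
  out <- S - outer(rm_, rm_) / gm
  diag(out) <- 0
  out
}

mean_field_scores <- function(mint, w, lambda) {
  fc <- frequency_counts(mint, w, lambda)
  L <- fc$L; q <- fc$q
  keep <- as.vector(vapply(seq_len(L), function(i)
    ((i - 1) * q + 1):((i - 1) * q + (q - 1)), integer(q - 1)))
  C <- fc$fij[keep, keep] -
    tcrossprod(fc$fi[keep])
  J <- tryCatch(-solve(C), error = function(e) {
    warning("singular correlation matrix; increasing pseudocount")
    fc2 <- frequency_counts(mint, w, min(0.9, lambda + 0.3))
    -solve(fc2$fij[keep, keep] - tcrossprod(fc2$fi[keep]))
  })
  S <- matrix(0, L, L)
  qm <- q - 1
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    blk <- J[((i - 1) * qm + 1):(i * qm), ((j - 1) * qm + 1):(j * qm)]
    S[i, j] <- S[j, i] <- frob_score(blk[seq_len(20), seq_len(20), drop = FALSE])
  }
  S
}

pseudolikelihood_scores <- function(mint, w, lambda_l2 = 0.01) {
  N <- nrow(mint); L <- ncol(mint); q <- N_STATES
  X <- matrix(0, N, L * q)
  X[cbind(rep(seq_len(N), L),
          (rep(seq_len(L), each = N) - 1L) * q + as.integer(mint))] <- 1
  # J[[r]]: q x (L*q) coupling estimates from site r's regression
  Jlist <- vector("list", L)
  for (r in seq_len(L)) {
    y <- factor(mint[, r], levels = seq_len(q))
    present <- as.integer(levels(droplevels(y)))
    if (length(present) < 2) { Jlist[[r]] <- matrix(0, q, L * q); next }
    Xr <- X[, -(((r - 1) * q + 1):(r * q)), drop = FALSE]
    fit <- glmnet::glmnet(Xr, droplevels(y), family = "multinomial",
                          alpha = 0, lambda = lambda_l2, weights = w,
                          standardize = FALSE)
    co <- glmnet::coef.glmnet(fit, s = lambda_l2)
    Jr <- matrix(0, q, L * q)
    other <- setdiff(seq_len(L * q), ((r - 1) * q + 1):(r * q))
    for (ai in seq_along(co))
      Jr[present[ai], other] <- as.numeric(co[[ai]])[-1]
    Jlist[[r]] <- Jr
  }
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    blk_i <- Jlist[[i]][seq_len(20), ((j - 1) * q + 1):((j - 1) * q + 20)]
    blk_j <- t(Jlist[[j]][seq_len(20), ((i - 1) * q + 1):((i - 1) * q + 20)])
    S[i, j] <- S[j, i] <- (frob_score(blk_i) + frob_score(blk_j)) / 2
  }
  S
}

#' Inter-protein evolutionary couplings from a concatenated MSA
#'
#' Direct-coupling analysis of the cMSA: sequences are redundancy-reweighted
#' (80% identity by default), columns with more than `max_gap_frac` gaps are
#' removed, couplings are estimated (mean-field inversion of the
#' pseudocount-regularized correlation matrix by default, or per-site
#' ridge-penalized pseudolikelihood), pair scores are the Frobenius norms of
#' the 20x20 amino-acid coupling blocks in zero-sum gauge (gap state
#' excluded), and the average-product correction removes background. Only
#' the inter-protein block (protein A column x protein B column) is
#' returned.
#'
#' @param cmsa A [concat_by_species()] result.
#' @param method `"mean_field"` (default) or `"pseudolikelihood"`.
#' @param lambda Relative pseudocount for the mean-field method.
#' @param reweight_id Fractional identity for sequence reweighting.
#' @param max_gap_frac Columns with a larger gap fraction are dropped.
#' @param lambda_l2 Ridge penalty for the pseudolikelihood method.
#' @return An object of class `coupling_map`: `raw` score matrix (rows =
#'   retained A columns, cols = retained B columns, dimnames carry original
#'   column indices), `convolved` (`NULL` until [gaussian_convolve()]),
#'   `boundary`, and `metadata`.
#' @export
compute_couplings <- function(cmsa, method = c("mean_field", "pseudolikelihood"),
                              lambda = 0.5, reweight_id = 0.8,
                              max_gap_frac = 0.5, lambda_l2 = 0.01) {
  stopifnot(inherits(cmsa, "concatenated_msa"))
  method <- match.arg(method)
  mint <- msa_to_int(cmsa$seqs)
  if (nrow(mint) < 50)
    warning(sprintf("only %d sequences; coupling estimates will be noisy",
                    nrow(mint)))
  gap_frac <- colMeans(mint == GAP_STATE)
  keep_cols <- which(gap_frac <= max_gap_frac)
  if (length(keep_cols) < ncol(mint))
    warning(sprintf("removed %d column(s) with > %.0f%% gaps",
                    ncol(mint) - length(keep_cols), 100 * max_gap_frac))
  mint <- mint[, keep_cols, drop = FALSE]
  w <- sequence_weights(mint, reweight_id)
  S <- if (method == "mean_field") mean_field_scores(mint, w, lambda)
       else pseudolikelihood_scores(mint, w, lambda_l2)
  S <- apc_correct(S)
  a_idx <- which(keep_cols <= cmsa$boundary)
  b_idx <- which(keep_cols > cmsa$boundary)
  if (!length(a_idx) || !length(b_idx))
    stop("no retained columns on one side of the boundary")
  raw <- S[a_idx, b_idx, drop = FALSE]
  dimnames(raw) <- list(keep_cols[a_idx], keep_cols[b_idx] - cmsa$boundary)
  structure(list(raw = raw, convolved = NULL, sigma = NULL,
                 boundary = cmsa$boundary,
                 metadata = list(method = method, lambda = lambda,
                                 reweight_id = reweight_id,
                                 n_seqs = length(cmsa$seqs),
                                 n_eff = sum(w),
                                 removed_cols = setdiff(seq_len(cmsa$len_a + cmsa$len_b),
                                                        keep_cols))),
            class = "coupling_map")
}

#' Gaussian convolution of an inter-protein coupling map
#'
#' Smooths the inter-protein score block with a normalized 2-D Gaussian
#' kernel (separable, reflective boundary), reinforcing spatially clustered
#' contact signal and suppressing isolated background noise.
#'
#' @param coupling_map A [compute_couplings()] result.
#' @param sigma Kernel standard deviation in columns (> 0).
#' @return The map with `convolved` filled in and `sigma` recorded.
#' @export
gaussian_convolve <- function(coupling_map, sigma = 2) {
  stopifnot(inherits(coupling_map, "coupling_map"), sigma > 0)
  conv <- gauss_filter2(unname(coupling_map$raw), sigma)
  dimnames(conv) <- dimnames(coupling_map$raw)
  coupling_map$convolved <- conv
  coupling_map$sigma <- sigma
  coupling_map
}

# Separable Gaussian filter with reflective padding; kernel sums to 1.
gauss_filter2 <- function(m, sigma) {
  R <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-R:R, sd = sigma)
  k <- k / sum(k)
  reflect_idx <- function(n) {
    i <- c(rev(seq_len(min(R, n))), seq_len(n), n + 1 - seq_len(min(R, n)))
    if (R > n) stop("kernel radius exceeds map extent")
    i
  }
  conv1 <- function(x) {   # filter each column of x
    n <- nrow(x)
    xp <- x[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (d in seq_along(k))
      out <- out + k[d] * xp[(d - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Minimum score of the top fraction of coupling scores
#'
#' Order-statistic threshold: the minimum value among the top
#' `ceiling(fraction * N)` scores. Values tied with the threshold are, by
#' construction, included when thresholding with `>=`.
#'
#' @param scores Numeric vector (>= 20 values).
#' @param fraction Top fraction (default 0.05).
#' @return The threshold value.
#' @export
top_fraction_threshold <- function(scores, fraction = 0.05) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20) stop("need at least 20 scores")
  m <- ceiling(fraction * length(scores))
  if (m < 1) stop("top fraction selects no scores")
  sort(scores, decreasing = TRUE)[m]
}

#' Top-ranked inter-protein pairs of a coupling map
#'
#' Contact identification ranks the unconvolved APC-corrected scores by
#' default: the Gaussian convolution deliberately trades per-pair
#' localization for spatial-cluster significance (a smoothed peak's kernel
#' neighbours outrank weaker genuine pairs), so it drives the interface
#' randomization test rather than individual contact calls.
#'
#' @param coupling_map A [compute_couplings()] result.
#' @param k Number of pairs.
#' @param which `"raw"` (default) or `"convolved"` scores.
#' @return Data.frame `i` (protein A column), `j` (protein B column),
#'   `score`, ordered by decreasing score.
#' @export
top_coupling_pairs <- function(coupling_map, k = 5,
                               which = c("raw", "convolved")) {
  which <- match.arg(which)
  S <- if (which == "convolved") {
    if (is.null(coupling_map$convolved)) stop("map has no convolved scores")
    coupling_map$convolved
  } else coupling_map$raw
  ord <- order(S, decreasing = TRUE)[seq_len(min(k, length(S)))]
  ij <- arrayInd(ord, dim(S))
  data.frame(i = as.integer(rownames(S))[ij[, 1]],
             j = as.integer(colnames(S))[ij[, 2]],
             score = S[ord])
}

#' Construct a randomization outcome
#'
#' Container for the species-shuffle significance test result; the p-value
#' follows the exceedances/replicates convention (`k/N`, so 3 exceedances
#' in 100 replicates give p = 0.03); the `(k+1)/(N+1)` estimate is reported
#' alongside.
#'
#' @param exceed_count Number of replicates exceeding the threshold.
#' @param n_replicates Number of replicates (>= 1).
#' @param threshold Threshold the replicates were compared against.
#' @param replicate_stats Optional per-replicate statistic values.
#' @param statistic Name of the exceedance statistic.
#' @return An object of class `randomization_outcome`.
#' @export
randomization_outcome <- function(exceed_count, n_replicates, threshold = NA,
                                  replicate_stats = NULL, statistic = NA) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  stopifnot(exceed_count >= 0, exceed_count <= n_replicates)
  structure(list(n_replicates = n_replicates, threshold = threshold,
                 exceed_count = exceed_count,
                 p_value = exceed_count / n_replicates,
                 p_value_plus = (exceed_count + 1) / (n_replicates + 1),
                 replicate_stats = replicate_stats, statistic = statistic),
            class = "randomization_outcome")
}

#' @export
print.randomization_outcome <- function(x, ...) {
  cat(sprintf("randomization test (%s): %d/%d exceedances, p = %g [(k+1)/(N+1) = %g]\n",
              x$statistic, x$exceed_count, x$n_replicates, x$p_value,
              x$p_value_plus))
  invisible(x)
}

#' Species-shuffle randomization test of an inter-protein coupling signal
#'
#' Tests whether the inter-protein coupling signal survives destruction of
#' the species pairing: protein A sequences are randomly reassigned to
#' species (protein B unchanged), the cMSA rebuilt and couplings plus
#' convolution recomputed for each of `n_replicates` replicates. The
#' threshold is the minimum convolved score of the top `fraction` of the
#' original signal. The default exceedance statistic asks whether a
#' replicate's maximum convolved score exceeds the threshold; `"count"`
#' asks whether at least as many pairs exceed the threshold as in the
#' original top set; `"top_min"` whether the minimum of the replicate's own
#' top-fraction set exceeds it. p = exceedances / replicates.
#'
#' @param set_a,set_b [ortholog_set()]s (A is shuffled).
#' @param n_replicates Number of randomized cMSAs (default 100).
#' @param sigma Convolution width.
#' @param fraction Top fraction defining the threshold.
#' @param statistic Exceedance statistic, see Details.
#' @param method Coupling method passed to [compute_couplings()].
#' @param seed Integer seed.
#' @param ... Further arguments to [compute_couplings()].
#' @return A list with the original `coupling_map`, `threshold`, and the
#'   [randomization_outcome()].
#' @export
randomization_test <- function(set_a, set_b, n_replicates = 100, sigma = 2,
                               fraction = 0.05,
                               statistic = c("max", "count", "top_min"),
                               method = "mean_field", seed = 1L, ...) {
  statistic <- match.arg(statistic)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed)
  cmsa <- concat_by_species(set_a, set_b)
  cmap <- gaussian_convolve(compute_couplings(cmsa, method = method, ...), sigma)
  thr <- top_fraction_threshold(as.vector(cmap$convolved), fraction)
  m <- ceiling(fraction * length(cmap$convolved))
  stats_vec <- numeric(n_replicates)
  for (b in seq_len(n_replicates)) {
    perm <- sample(length(set_a$seqs))
    shuffled <- set_a$seqs[perm]
    names(shuffled) <- set_a$species
    set_a_perm <- ortholog_set(shuffled)
    cm_b <- suppressWarnings(
      gaussian_convolve(compute_couplings(concat_by_species(set_a_perm, set_b),
                                          method = method, ...), sigma))
    v <- as.vector(cm_b$convolved)
    stats_vec[b] <- switch(statistic,
                           max = max(v),
                           count = sum(v > thr),
                           top_min = sort(v, decreasing = TRUE)[min(m, length(v))])
  }
  exceed <- switch(statistic,
                   max = sum(stats_vec > thr),
                   count = sum(stats_vec >= m),
                   top_min = sum(stats_vec > thr))
  list(coupling_map = cmap, threshold = thr,
       outcome = randomization_outcome(exceed, n_replicates, thr,
                                       stats_vec, statistic))
}

#' Simulate a pair of coevolving ortholog sets
#'
#' Generates two protein alignments evolved down a shared random coalescent
#' tree: every column substitutes independently along branches, except the
#' planted inter-protein column pairs, whose protein-B member tracks the
#' protein-A member through a pair-specific residue mapping with
#' probability `coupling_strength` per species (and evolves independently
#' otherwise). Shared ancestry supplies realistic phylogenetic background
#' correlation; the planted pairs are the ground-truth interface.
#'
#' @param len_a,len_b Alignment lengths.
#' @param n_species Number of species (tree tips).
#' @param n_planted Number of planted inter-protein pairs (ignored when
#'   `planted_pairs` is given).
#' @param planted_pairs Optional 2-column matrix of (A column, B column).
#' @param coupling_strength Per-species probability that the B column
#'   mirrors the A column, in `[0, 1]`.
#' @param mutation_rate Expected substitutions per column over a unit of
#'   tree depth.
#' @param tree_depth Root-to-tip depth the coalescent tree is scaled to.
#' @param seed Integer seed.
#' @return A list with `set_a`, `set_b` ([ortholog_set()]s), and `truth`
#'   (`pairs` matrix and per-pair residue maps).
#' @export
generate_coevolving_msa <- function(len_a = 60, len_b = 60, n_species = 500,
                                    n_planted = 5, planted_pairs = NULL,
                                    coupling_strength = 0.9,
                                    mutation_rate = 6, tree_depth = 1,
                                    seed = 1L) {
  set.seed(seed)
  if (is.null(planted_pairs) && n_planted > 0) {
    planted_pairs <- cbind(sample(len_a, n_planted),
                           sample(len_b, n_planted))
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2)
    stopifnot(all(planted_pairs[, 1] >= 1), all(planted_pairs[, 1] <= len_a),
              all(planted_pairs[, 2] >= 1), all(planted_pairs[, 2] <= len_b))
  }
  L <- len_a + len_b
  tree <- ape::rcoal(n_species)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * tree_depth
  n_nodes <- n_species + tree$Nnode
  states <- matrix(0L, n_nodes, L)
  root <- n_species + 1L
  states[root, ] <- sample(20L, L, replace = TRUE)
  # preorder: parents before children
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])
  for (ei in ord) {
    parent <- tree$edge[ei, 1]; child <- tree$edge[ei, 2]
    len <- tree$edge.length[ei]
    s <- states[parent, ]
    mut <- stats::runif(L) < (1 - exp(-mutation_rate * len))
    s[mut] <- sample(20L, sum(mut), replace = TRUE)
    states[child, ] <- s
  }
  leaves <- states[seq_len(n_species), , drop = FALSE]
  # species labels are assigned to tips at random: coalescent tip numbering
  # correlates with topology, which would otherwise leak relatedness
  # through the label index itself
  leaves <- leaves[sample(n_species), , drop = FALSE]
  maps <- list()
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
    for (p in seq_len(nrow(planted_pairs))) {
      i <- planted_pairs[p, 1]; j <- len_a + planted_pairs[p, 2]
      sigma_p <- sample(20L)
      follow <- stats::runif(n_species) < coupling_strength
      leaves[follow, j] <- sigma_p[leaves[follow, i]]
      maps[[p]] <- sigma_p
    }
  }
  species <- sprintf("SP%04d", seq_len(n_species))
  to_seq <- function(cols) {
    apply(leaves[, cols, drop = FALSE], 1, function(r)
      paste(AA_ALPHABET[r], collapse = ""))
  }
  sa <- to_seq(seq_len(len_a)); names(sa) <- species
  sb <- to_seq(len_a + seq_len(len_b)); names(sb) <- species
  list(set_a = ortholog_set(sa), set_b = ortholog_set(sb),
       truth = list(pairs = planted_pairs, maps = maps,
                    coupling_strength = coupling_strength))
}
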