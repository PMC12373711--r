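#' Inter-subject metabolic connectivity matrix
#'
#' Metabolic connectivity at the group level: the Pearson correlation,
#' across the subjects of one group, between the SUVmean of each pair of
#' nodes (regions or networks). There is no per-subject connectome — the
#' edge is a property of the group sample.
#'
#' @param suv subjects x nodes numeric matrix (>= 3 subjects, named
#'   columns, every column with positive variance).
#' @return Object of class \code{connectivity_matrix}: \code{labels},
#'   \code{r} (symmetric, unit diagonal), \code{n_subjects}.
#' @export
connectivity_matrix <- function(suv) {
  suv <- as.matrix(suv)
  if (nrow(suv) < 3L) stop("need at least 3 subjects")
  if (is.null(colnames(suv))) colnames(suv) <- paste0("V", seq_len(ncol(suv)))
  vars <- apply(suv, 2L, stats::var)
  if (any(vars == 0))
    stop("zero-variance node(s): ",
         paste(colnames(suv)[vars == 0], collapse = ", "))
  r <- stats::cor(suv)
  structure(list(labels = colnames(suv), r = r, n_subjects = nrow(suv)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix:", length(x$labels), "nodes,",
      x$n_subjects, "subjects\n")
  invisible(x)
}

# stable 31-based string hash into [0, 2^31 - 2]; used to derive
# per-analysis RNG streams from one master seed so adding an analysis
# never perturbs another's permutations
stable_string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a master seed and a label
#' @param master integer master seed.
#' @param label character tag of the analysis (e.g. a network name).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, label) {
  as.integer((as.numeric(master) + stable_string_hash(label)) %% 2147483647)
}

#' Permutation test on connectivity edges
#'
#' For every node pair, the observed statistic is the raw correlation
#' difference delta = r(group1) - r(group2). The null is built by pooling
#' all subjects, re-splitting at random into the original group sizes B
#' times, and recomputing delta; the two-tailed p is
#' (#\{|delta*| >= |delta_obs|\} + 1) / (B + 1) (add-one correction, so
#' p >= 1/(B+1) > 0). BH-FDR is applied across the edges of the family.
#' The pooled sample is put into a canonical row order before resampling,
#' so results do not depend on how subjects are ordered within a group.
#'
#' @param suv1,suv2 subjects x nodes matrices for the two groups
#'   (identical node sets, >= 3 subjects each).
#' @param B number of permutations (>= 1; the conventional default used
#'   throughout the package is 10000).
#' @param seed integer seed; identical inputs + B + seed give identical
#'   results.
#' @return data.frame(node_i, node_j, r1, r2, delta, p, q), one row per
#'   unordered pair.
#' @export
edge_permutation_test <- function(suv1, suv2, B = 10000L, seed = 1L) {
  suv1 <- as.matrix(suv1); suv2 <- as.matrix(suv2)
  if (!identical(colnames(suv1), colnames(suv2)))
    stop("the two groups must share an identical node set")
  if (nrow(suv1) < 3L || nrow(suv2) < 3L)
    stop("need at least 3 subjects per group")
  if (B < 1L) stop("B must be >= 1")

  k <- ncol(suv1)
  if (k < 2L) stop("need at least 2 nodes")
  ut <- upper.tri(matrix(0, k, k))
  r1 <- stats::cor(suv1); r2 <- stats::cor(suv2)
  delta_obs <- (r1 - r2)[ut]

  pooled <- rbind(suv1, suv2)
  # canonicalize row order (lexicographic) so the resampled null — and
  # hence every p — is invariant to how subjects happen to be ordered
  # within each group; identical rows are exchangeable so ties are inert
  pooled <- pooled[do.call(order, as.data.frame(pooled)), , drop = FALSE]
  n <- nrow(pooled); n1 <- nrow(suv1)
  exceed <- numeric(length(delta_obs))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    d <- (stats::cor(pooled[idx, , drop = FALSE]) -
            stats::cor(pooled[-idx, , drop = FALSE]))[ut]
    exceed <- exceed + (abs(d) >= abs(delta_obs))
  }
  p <- (exceed + 1) / (B + 1)

  pairs <- which(ut, arr.ind = TRUE)
  labels <- colnames(suv1)
  data.frame(node_i = labels[pairs[, 1]], node_j = labels[pairs[, 2]],
             r1 = r1[ut], r2 = r2[ut], delta = delta_obs,
             p = p, q = fdr_bh(p), stringsAsFactors = FALSE)
}

#' Per-network intra-network edge comparison
#'
#' Runs \code{\link{edge_permutation_test}} on the member regions of each
#' of the seven networks separately (one correlation matrix per network,
#' one FDR family per network). RNG streams are derived per network from
#' the master seed by a stable hash of the network name.
#'
#' @param cohort a \code{cohort_table} with both groups.
#' @param atlas an \code{atlas_definition}.
#' @param B permutations per network.
#' @param seed master seed.
#' @return Named list of edge-stat data.frames, one per network with >= 2
#'   member regions.
#' @export
intranetwork_edges <- function(cohort, atlas, B = 10000L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  g1 <- cohort$group_labels[1]; g2 <- cohort$group_labels[2]
  out <- list()
  for (net in YEO7_NETWORKS) {
    members <- atlas$regions$abbreviation[atlas$regions$network == net]
    members <- intersect(members, colnames(cohort$suv))
    if (length(members) < 2L) next
    out[[net]] <- edge_permutation_test(
      group_suv(cohort, g1)[, members, drop = FALSE],
      group_suv(cohort, g2)[, members, drop = FALSE],
      B = B, seed = derive_seed(seed, net))
  }
  out
}

#' Inter-network edge comparison
#'
#' The seven whole-network SUVmeans act as nodes; the 21 network-pair
#' edges form one FDR family.
#'
#' @param networks a \code{network_table} with both groups (or pass
#'   \code{networks1}/\code{networks2} matrices directly).
#' @param B permutations.
#' @param seed master seed (stream tag "internetwork").
#' @return Edge-stat data.frame with 21 rows.
#' @export
internetwork_connectivity <- function(networks, B = 10000L, seed = 1L) {
  stopifnot(inherits(networks, "network_table"))
  g1 <- networks$group_labels[1]; g2 <- networks$group_labels[2]
  edge_permutation_test(group_network_suv(networks, g1),
                        group_network_suv(networks, g2),
                        B = B, seed = derive_seed(seed, "internetwork"))
}

#' Write a connectivity matrix as a labeled square TSV
#' @param cm a \code{connectivity_matrix}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(node = cm$labels, cm$r, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
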