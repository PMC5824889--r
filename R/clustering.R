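## UPGMA clustering of metabolite profiles with bootstrap clade support,
## including "approximately unbiased" p-values via multiscale bootstrap.

#' Pairwise distance matrix between profile columns
#'
#' `"cosine"` (default): bitvector cosine distance on the binarised columns,
#' `1 - |a AND b| / sqrt(|a| |b|)`, in \[0, 1\]. Zero-vector conventions:
#' distance 1 against any non-zero profile, 0 against another zero profile.
#' `"euclidean"`: ordinary Euclidean distance on the count profiles.
#'
#' @param mat An [occurrence_matrix()] (columns are the objects clustered).
#' @param metric `"cosine"` or `"euclidean"`.
#' @return A `stats::dist` object over the columns.
#' @export
profile_distance_matrix <- function(mat, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  m <- unclass(mat)
  if (ncol(m) == 0L || nrow(m) == 0L) stop("empty matrix", call. = FALSE)
  if (metric == "euclidean") return(stats::dist(t(m)))
  b <- (m > 0) * 1
  cp <- crossprod(b)
  sizes <- diag(cp)
  denom <- sqrt(outer(sizes, sizes))
  sim <- ifelse(denom > 0, cp / denom, 0)
  sim[sizes == 0, sizes == 0] <- 1      # two empty profiles: distance 0
  d <- 1 - sim
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration via [stats::hclust()]. Merge heights are
#' reported as ultrametric node heights (half the average linkage distance),
#' so two leaves at distance d merge at height d/2 and cophenetic distances
#' equal twice the node heights. Ties are resolved by hclust's deterministic
#' merge order.
#'
#' @param d A `stats::dist` over >= 2 objects (no missing values).
#' @return An object of class `"upgma"`: list with `hclust` (heights in
#'   distance units), `height` (ultrametric node heights), `labels`,
#'   `merge`, and `phylo` (an ultrametric [ape] tree).
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("need at least 2 objects", call. = FALSE)
  if (anyNA(d)) stop("distance matrix contains missing values", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  hc2 <- hc
  hc2$height <- hc$height / 2
  phylo <- ape::as.phylo(hc2)
  structure(list(hclust = hc, height = hc2$height, labels = hc$labels,
                 merge = hc$merge, phylo = phylo),
            class = "upgma")
}

#' @export
print.upgma <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$labels), "leaves; root height",
      signif(max(x$height), 4), "\n")
  invisible(x)
}

#' Cophenetic distances and cophenetic correlation
#'
#' @param tree An `"upgma"` object.
#' @return [cophenetic_distances()]: the cophenetic `dist` (in the units of
#'   the input distances). [cophenetic_correlation()]: Pearson correlation
#'   between the cophenetic and the input distances.
#' @export
cophenetic_distances <- function(tree) {
  stats::cophenetic(tree$hclust)
}

#' @rdname cophenetic_distances
#' @param d The distance matrix the tree was built from.
#' @export
cophenetic_correlation <- function(tree, d) {
  stats::cor(as.vector(cophenetic_distances(tree)), as.vector(d))
}

build_tree <- function(mat, metric) {
  upgma(profile_distance_matrix(mat, metric))$phylo
}

# Clade (bipartition) frequency of each internal node of `ref` among `trees`.
clade_frequencies <- function(ref, trees) {
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = TRUE)
  counts[is.na(counts)] <- 0
  counts / length(trees)
}

# Shimodaira multiscale-bootstrap fit for one clade:
# qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r); AU = 1 - pnorm(v - c).
fit_au <- function(bp, r, n_boot) {
  eps <- 1 / (2 * n_boot)
  if (all(bp >= 1 - eps)) return(1)
  if (all(bp <= eps)) return(0)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  w <- n_boot * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]
  cc <- fit$coefficients[2]
  if (anyNA(c(v, cc))) return(mean(bp))
  unname(1 - stats::pnorm(v - cc))
}

#' Bootstrap clade support for UPGMA column clustering
#'
#' Rows (buckets or compound families) are resampled with replacement, the
#' tree is rebuilt per replicate, and the support of each clade of the
#' point-estimate tree is its bipartition frequency among the replicates
#' (BP). With `method = "au"`, the multiscale bootstrap is run at scales
#' r in \{0.5, 0.6, ..., 1.4\} (resample size round(r * nrow)) and the
#' approximately unbiased p-value is obtained from the signed-distance /
#' curvature fit z(r) = v sqrt(r) + c / sqrt(r), AU = 1 - Phi(v - c).
#'
#' @param mat An [occurrence_matrix()]; columns are clustered.
#' @param n_boot Bootstrap replicates per scale (default 500).
#' @param method `"bp"` or `"au"` (AU also reports BP at scale 1).
#' @param metric Distance metric, see [profile_distance_matrix()].
#' @param seed Optional integer seed.
#' @return `list(tree = "upgma" object, support = tibble(node, bp[, au]),
#'   newick = Newick string with BP percentages as node labels)`.
#' @export
bootstrap_support <- function(mat, n_boot = 500L, method = c("bp", "au"),
                              metric = "cosine", seed = NULL) {
  method <- match.arg(method)
  m <- unclass(mat)
  if (ncol(m) < 3L) stop("need at least 3 columns to support clades",
                         call. = FALSE)
  tree <- upgma(profile_distance_matrix(mat, metric))
  ref <- tree$phylo
  scales <- if (method == "bp") 1 else seq(0.5, 1.4, by = 0.1)
  run <- function() {
    lapply(scales, function(r) {
      size <- max(2L, round(r * nrow(m)))
      trees <- lapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(m), size, replace = TRUE)
        build_tree(m[idx, , drop = FALSE], metric)
      })
      clade_frequencies(ref, trees)
    })
  }
  freq <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_nodes <- length(freq[[1]])
  bp_main <- freq[[which.min(abs(scales - 1))]]
  support <- tibble::tibble(
    node = length(ref$tip.label) + seq_len(n_nodes), bp = bp_main)
  if (method == "au") {
    r_eff <- vapply(scales, function(r)
      max(2L, round(r * nrow(m))) / nrow(m), numeric(1))
    bp_mat <- do.call(rbind, freq)
    support$au <- vapply(seq_len(n_nodes), function(j)
      fit_au(bp_mat[, j], r_eff, n_boot), numeric(1))
  }
  annotated <- ref
  annotated$node.label <- sprintf("%.0f", support$bp * 100)
  list(tree = tree, support = support,
       newick = ape::write.tree(annotated))
}

#' Write a support-annotated dendrogram as Newick
#'
#' @param result A result list from [bootstrap_support()].
#' @param path Output file.
#' @export
write_newick <- function(result, path) {
  writeLines(result$newick, path)
  invisible(path)
}
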