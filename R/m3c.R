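## Monte Carlo reference-based consensus clustering.
##
## For each candidate k the real data are consensus-clustered (resampled
## hierarchical clustering); stability is summarised by the PAC score
## (proportion of ambiguous clustering). The same machinery is applied to
## reference datasets simulated from a structure-free null that preserves
## the data's mean and covariance, giving a reference PAC distribution per
## k. The relative cluster stability index RCSI_k = ln(mean reference PAC /
## real PAC) and an empirical p-value decide whether k-way structure is
## real; the selected k is the significant k with the highest RCSI, or
## "homogeneous" when no k reaches significance.

## Run RNG-consuming code under a private seed, restoring the caller's RNG
## state afterwards so package functions never perturb user randomness.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Consensus matrix by resampled hierarchical clustering
#'
#' Repeatedly subsamples the objects, clusters each subsample
#' (agglomerative, Euclidean distance) and cuts at `k`; consensus entry
#' (i, j) is the fraction of iterations in which i and j co-clustered among
#' those where both were sampled. Pairs never co-sampled are set to 0 with a
#' logged count. Works for univariate (single-feature) input.
#'
#' @param values numeric objects-by-features matrix (or vector).
#' @param k number of clusters to cut at (`k <=` number of objects).
#' @param iterations number of resampling iterations.
#' @param resample_fraction fraction of objects drawn (without replacement)
#'   per iteration.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return symmetric n x n consensus matrix with unit diagonal.
#' @export
consensus_cluster <- function(values, k, iterations = 100,
                              resample_fraction = 0.8, linkage = "complete") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (k > n) stop("k (", k, ") exceeds the number of objects (", n, ")",
                  call. = FALSE)
  stopifnot(iterations >= 1, resample_fraction > 0, resample_fraction <= 1)
  m <- max(2L, min(n, round(resample_fraction * n)))
  co <- matrix(0, n, n)     # co-cluster counts
  both <- matrix(0, n, n)   # co-sample counts
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, m)
    lab <- cutree(hclust(dist(values[idx, , drop = FALSE]), method = linkage),
                  k = min(k, m))
    same <- outer(lab, lab, "==")
    co[idx, idx] <- co[idx, idx] + same
    both[idx, idx] <- both[idx, idx] + 1
  }
  never <- both == 0
  if (any(never[upper.tri(never)]))
    prism_log(sum(never[upper.tri(never)]),
              " object pair(s) never co-sampled; consensus set to 0")
  both[never] <- 1
  cons <- co / both
  cons[never] <- 0
  diag(cons) <- 1
  cons
}

#' PAC score (proportion of ambiguous clustering)
#'
#' Fraction of off-diagonal consensus entries strictly inside the ambiguity
#' window `(lower, upper)`: 0 means perfectly stable clustering (every pair
#' either always or never co-clusters).
#'
#' @param consensus square consensus matrix (entries in `[0, 1]`).
#' @param lower,upper ambiguity window bounds.
#' @return PAC fraction in `[0, 1]`.
#' @export
pac_score <- function(consensus, lower = 0.1, upper = 0.9) {
  consensus <- as.matrix(consensus)
  if (nrow(consensus) < 2L)
    stop("PAC is undefined for a 1 x 1 consensus matrix", call. = FALSE)
  off <- consensus[upper.tri(consensus)]
  mean(off > lower & off < upper)
}

#' Simulate a structure-free reference dataset
#'
#' Draws a same-shape dataset from a null with no subpopulation structure
#' that preserves the data's location and covariance scale: a multivariate
#' normal with the sample mean vector and covariance, sampled in
#' principal-component space (for univariate input this is a normal with the
#' sample mean and sd). `method = "permute"` instead permutes each column
#' independently, an alternative null that preserves marginals exactly.
#'
#' @param values numeric objects-by-features matrix (or vector).
#' @param method `"pca-normal"` (default) or `"permute"`.
#' @return matrix of the same dimensions.
#' @export
simulate_reference <- function(values, method = c("pca-normal", "permute")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (n < 3L) stop("need at least 3 objects to fit a reference null", call. = FALSE)
  if (method == "permute")
    return(apply(values, 2, sample))
  mu <- colMeans(values)
  if (p == 1L)
    return(matrix(rnorm(n, mu, sd(values)), ncol = 1))
  eg <- eigen(cov(values), symmetric = TRUE)
  lam <- eg$values
  if (any(lam < .Machine$double.eps * max(lam))) {
    prism_log("near-singular covariance; reference falls back to diagonal covariance")
    sds <- apply(values, 2, sd)
    out <- matrix(rnorm(n * p), n, p) %*% diag(sds, p)
    return(sweep(out, 2, mu, "+"))
  }
  z <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(lam), p)
  sweep(z %*% t(eg$vectors), 2, mu, "+")
}

#' Monte Carlo reference-based consensus clustering
#'
#' For each k in `2..max_k`, computes the real-data PAC and a reference PAC
#' distribution over `ref_iterations` simulated null datasets (each
#' consensus-clustered with the same number of resampling iterations as the
#' real data). Reports per k:
#' \describe{
#'   \item{rcsi}{`log(mean(reference PAC) / real PAC)`, with a small floor
#'     `pac_eps` on PAC values so the ratio is always finite.}
#'   \item{p_value}{add-one-corrected empirical p,
#'     `(1 + #\{reference PAC <= real PAC\}) / (ref_iterations + 1)` — always
#'     positive, so `p < 0.01` is attainable only with >= 100 reference
#'     iterations.}
#' }
#' The selected k is the k with the highest RCSI among those with
#' `p < p_threshold`; if none qualifies the population is called
#' `"homogeneous"`. Cluster assignments at the selected k come from
#' hierarchically clustering the consensus dissimilarity `1 - consensus`.
#'
#' Results are deterministic for a given seed and invariant to object order
#' (objects are canonically ordered internally before any random draw).
#'
#' @param values numeric objects-by-features matrix or vector (univariate
#'   per-feature use is the common case).
#' @param max_k largest candidate cluster number (default 8).
#' @param iterations real-data consensus resampling iterations (default 200).
#' @param ref_iterations number of simulated reference datasets (default 200).
#' @param resample_fraction subsampling fraction per consensus iteration.
#' @param linkage [stats::hclust()] agglomeration method.
#' @param seed RNG seed (default 42); the caller's RNG state is untouched.
#' @param p_threshold significance level for a candidate k (default 0.01).
#' @param pac_window ambiguity window for [pac_score()].
#' @param pac_eps floor applied to PAC values inside the RCSI ratio.
#' @param ref_method reference null passed to [simulate_reference()].
#' @param repeats independent repetitions of the whole procedure; if > 1 the
#'   reported selection is the majority vote across repeats (the first
#'   repeat's diagnostics are returned).
#' @return object of class `m3c`: list with `per_k` (data.frame `k`,
#'   `pac_real`, `pac_ref_mean`, `rcsi`, `p_value`), `pac_reference` (list of
#'   reference PAC vectors per k), `consensus` (list of consensus matrices
#'   per k), `selected_k` (integer or `"homogeneous"`), `assignments`
#'   (integer cluster labels, `NULL` when homogeneous) and the configuration.
#' @export
run_m3c <- function(values, max_k = 8, iterations = 200, ref_iterations = 200,
                    resample_fraction = 0.8, linkage = "complete", seed = 42,
                    p_threshold = 0.01, pac_window = c(0.1, 0.9),
                    pac_eps = 1e-4, ref_method = "pca-normal", repeats = 1) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (max_k < 2) stop("max_k must be at least 2", call. = FALSE)
  if (n < max_k + 1L)
    stop("need at least max_k + 1 objects (", max_k + 1L, "), got ", n,
         call. = FALSE)
  # canonical object order: selection becomes invariant to input order
  ord <- do.call(order, as.data.frame(values))
  inv <- order(ord)
  v <- values[ord, , drop = FALSE]

  one_run <- function(run_seed) with_private_seed(run_seed, {
    ks <- 2:max_k
    pac_real <- numeric(length(ks))
    consensus <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      consensus[[i]] <- consensus_cluster(v, ks[i], iterations,
                                          resample_fraction, linkage)
      pac_real[i] <- pac_score(consensus[[i]], pac_window[1], pac_window[2])
    }
    pac_ref <- matrix(0, ref_iterations, length(ks))
    for (r in seq_len(ref_iterations)) {
      ref <- simulate_reference(v, method = ref_method)
      for (i in seq_along(ks))
        pac_ref[r, i] <- pac_score(
          consensus_cluster(ref, ks[i], iterations, resample_fraction, linkage),
          pac_window[1], pac_window[2])
    }
    rcsi <- log(pmax(colMeans(pac_ref), pac_eps) / pmax(pac_real, pac_eps))
    p_value <- vapply(seq_along(ks), function(i)
      (1 + sum(pac_ref[, i] <= pac_real[i])) / (ref_iterations + 1), numeric(1))
    sig <- p_value < p_threshold
    selected <- if (any(sig)) ks[sig][which.max(rcsi[sig])] else "homogeneous"
    list(per_k = data.frame(k = ks, pac_real = pac_real,
                            pac_ref_mean = colMeans(pac_ref),
                            rcsi = rcsi, p_value = p_value),
         pac_reference = lapply(seq_along(ks), function(i) pac_ref[, i]),
         consensus = consensus, selected_k = selected)
  })

  runs <- lapply(seq_len(repeats), function(r) one_run(seed + r - 1L))
  sel <- vapply(runs, function(r) as.character(r$selected_k), character(1))
  votes <- sort(table(sel), decreasing = TRUE)
  selected <- names(votes)[1]
  if (repeats > 1)
    prism_log("majority vote over ", repeats, " repeats: ",
              paste(names(votes), votes, sep = " x ", collapse = ", "))
  if (selected != "homogeneous") selected <- as.integer(selected)
  res <- runs[[1]]

  assignments <- NULL
  if (!identical(selected, "homogeneous")) {
    ki <- match(selected, res$per_k$k)
    cons <- res$consensus[[ki]]
    lab <- cutree(hclust(as.dist(1 - cons), method = linkage), k = selected)
    # canonical labels: clusters numbered by first appearance
    lab <- as.integer(factor(lab, levels = unique(lab)))
    assignments <- lab[inv]
  }
  structure(list(per_k = res$per_k, pac_reference = res$pac_reference,
                 consensus = lapply(res$consensus, function(m)
                   m[inv, inv, drop = FALSE]),
                 selected_k = selected, assignments = assignments,
                 n_objects = n,
                 config = list(max_k = max_k, iterations = iterations,
                               ref_iterations = ref_iterations,
                               resample_fraction = resample_fraction,
                               linkage = linkage, seed = seed,
                               p_threshold = p_threshold,
                               pac_window = pac_window, pac_eps = pac_eps,
                               ref_method = ref_method, repeats = repeats)),
            class = "m3c")
}

#' @export
print.m3c <- function(x, ...) {
  cat(sprintf("<m3c: %d objects, k in 2..%d, %d/%d iterations, seed %d>\n",
              x$n_objects, x$config$max_k, x$config$iterations,
              x$config$ref_iterations, x$config$seed))
  cat("selected k:",
      if (identical(x$selected_k, "homogeneous")) "homogeneous (no subclustering)"
      else x$selected_k, "\n")
  invisible(x)
}

#' @export
summary.m3c <- function(object, ...) {
  cat("Monte Carlo reference-based consensus clustering\n")
  print(object$per_k, row.names = FALSE, digits = 4)
  cat("selected k:",
      if (identical(object$selected_k, "homogeneous")) "homogeneous"
      else object$selected_k, "\n")
  invisible(object$per_k)
}

#' Plot RCSI and p-value against candidate k
#'
#' @param x `m3c` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.m3c <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sig <- x$per_k$p_value < x$config$p_threshold
  graphics::plot(x$per_k$k, x$per_k$rcsi, type = "b", xlab = "k",
                 ylab = "RCSI", pch = ifelse(sig, 19, 1), ...)
  if (!identical(x$selected_k, "homogeneous"))
    graphics::abline(v = x$selected_k, lty = 2)
  graphics::plot(x$per_k$k, x$per_k$p_value, type = "b", log = "y",
                 xlab = "k", ylab = "empirical p", ...)
  graphics::abline(h = x$config$p_threshold, lty = 2)
  invisible(x)
}
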