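#' Ward merge cost between two clusters
#'
#' The increase in total within-cluster sum of squared distances to the
#' centroid caused by merging: `SS(Ci u Cj) - SS(Ci) - SS(Cj)`. Always
#' non-negative; equals `|Ci||Cj| / (|Ci| + |Cj|) * ||ri - rj||^2`.
#'
#' @param ci,cj numeric matrices, one member vector per row (a plain vector
#'   is treated as a single member).
#' @return non-negative scalar merge cost.
#' @export
ward_merge_cost <- function(ci, cj) {
  if (is.vector(ci)) ci <- matrix(ci, nrow = 1)
  if (is.vector(cj)) cj <- matrix(cj, nrow = 1)
  if (nrow(ci) == 0L || nrow(cj) == 0L) stop("empty cluster")
  ss <- function(m) {
    ctr <- colMeans(m)
    sum(sweep(m, 2, ctr)^2)
  }
  ss(rbind(ci, cj)) - ss(ci) - ss(cj)
}

#' Bottom-up Ward agglomeration of trend curves
#'
#' Classic agglomerative clustering: every series starts as a singleton and
#' the pair with minimal [ward_merge_cost()] is merged at each step
#' (Lance-Williams update), with ties broken on the smallest pair of cluster
#' indices so the result is deterministic given input order. Merge heights
#' (the merge costs) are non-decreasing along the agglomeration.
#'
#' `k = "auto"` picks the cut with the largest relative gap between
#' successive merge heights (the visual dendrogram criterion), searched over
#' `2..min(10, n - 1)` clusters.
#'
#' @param x numeric matrix, one series per row.
#' @param k integer number of groups (default 4) or `"auto"`.
#' @return object of class `ward_clustering`: list with `labels` (1..k,
#'   numbered by smallest member index), `k`, `merges` (data.table `step`,
#'   `a`, `b`, `height`; ids <= n are singletons, larger ids refer to the
#'   cluster created at step `id - n`), `heights`, `centroids` (k x p).
#' @export
ward_agglomerate <- function(x, k = 4) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least two series")
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k > n) stop("k exceeds the number of series")
    if (k < 1L) stop("k must be positive")
  }

  ## cost matrix between active clusters, indexed by slot 1..n
  d <- as.matrix(dist(x))^2 / 2          # singleton Ward cost
  diag(d) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  ids <- seq_len(n)                       # dendrogram id carried by each slot
  merges <- data.table(step = integer(n - 1L), a = integer(n - 1L),
                       b = integer(n - 1L), height = numeric(n - 1L))
  members <- as.list(seq_len(n))          # original row indices per slot

  for (step in seq_len(n - 1L)) {
    dv <- d
    dv[!active, ] <- Inf
    dv[, !active] <- Inf
    m <- min(dv)
    cand <- which(dv == m, arr.ind = TRUE)
    ## tie-break: smallest (id_i, id_j) pair
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- order(pmin(ids[cand[, 1]], ids[cand[, 2]]),
                 pmax(ids[cand[, 1]], ids[cand[, 2]]))
    i <- cand[key[1], 1]; j <- cand[key[1], 2]

    merges[step, `:=`(step = step,
                      a = min(ids[i], ids[j]),
                      b = max(ids[i], ids[j]),
                      height = m)]
    ## Lance-Williams update for Ward merge costs
    ni <- sizes[i]; nj <- sizes[j]
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    for (o in others) {
      no <- sizes[o]
      d[i, o] <- d[o, i] <-
        ((ni + no) * d[i, o] + (nj + no) * d[j, o] - no * d[i, j]) /
        (ni + nj + no)
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    ids[i] <- n + step
    members[[i]] <- c(members[[i]], members[[j]])
  }

  heights <- merges$height
  if (identical(k, "auto")) {
    kmax <- min(10L, n - 1L)
    gaps <- vapply(2:kmax, function(kk) {
      lo <- heights[n - kk]
      hi <- heights[n - kk + 1L]
      hi / max(lo, .Machine$double.eps)
    }, numeric(1))
    k <- (2:kmax)[which.max(gaps)]
  }

  labels <- cut_ward_merges(merges, n, k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  structure(list(labels = labels, k = k, merges = merges, heights = heights,
                 n = n, centroids = centroids),
            class = "ward_clustering")
}

#' Cut a merge history into k groups
#'
#' Replays the first `n - k` merges; groups are numbered 1..k in order of
#' their smallest original member index.
#'
#' @param merges merge table from [ward_agglomerate()].
#' @param n number of original series.
#' @param k number of groups.
#' @return integer label vector of length n.
#' @export
cut_ward_merges <- function(merges, n, k) {
  stopifnot(k >= 1, k <= n)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nsteps <- n - k
  for (s in seq_len(nsteps)) {
    a <- find(merges$a[s]); b <- find(merges$b[s])
    parent[a] <- n + s
    parent[b] <- n + s
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ## label groups by smallest member index
  first <- tapply(seq_len(n), roots, min)
  ord <- rank(first)
  labels <- unname(ord[as.character(roots)])
  as.integer(labels)
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> n = %d, k = %d (sizes: %s)\n", x$n, x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Name cluster groups by response-curve shape
#'
#' Maps anonymous group labels onto the four disaster-response archetypes
#' using each group's mean curve: a peak |deviation| below `stable_max` is
#' stable (a flat curve's peak sign is sampling noise, so magnitude is
#' checked first); otherwise a positive peak marks shelter-in-place; among
#' the remaining dipping groups a persistent terminal deficit (mean of the
#' last `tail_days` below `abandoned_tail`) is abandoned, and the remainder
#' is distressed.
#'
#' @param x trend matrix (series per row) used for the clustering.
#' @param labels integer group labels.
#' @param impact_idx optional column indices of the impact window (default:
#'   whole series) over which the peak is taken.
#' @param stable_max peak-|deviation| ceiling for "stable" (default 0.2).
#' @param abandoned_tail terminal-deviation ceiling for "abandoned"
#'   (default -0.125).
#' @param tail_days days averaged for the terminal level (default 7).
#' @return character vector: archetype name per group label 1..k.
#' @export
label_archetypes <- function(x, labels, impact_idx = NULL,
                             stable_max = 0.2, abandoned_tail = -0.125,
                             tail_days = 7) {
  x <- as.matrix(x)
  if (is.null(impact_idx)) impact_idx <- seq_len(ncol(x))
  k <- max(labels)
  vapply(seq_len(k), function(g) {
    curve <- colMeans(x[labels == g, , drop = FALSE])
    win <- curve[impact_idx]
    peak <- win[which.max(abs(win))]
    terminal <- mean(tail(curve, tail_days))
    if (abs(peak) < stable_max) "stable"
    else if (peak > 0) "shelter_in_place"
    else if (terminal <= abandoned_tail) "abandoned"
    else "distressed"
  }, character(1))
}
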