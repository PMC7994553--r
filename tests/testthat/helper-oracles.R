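## Independent oracles used to cross-check the package implementations.
library(data.table)

## Brute-force DBSCAN: density connectivity via boolean transitive closure
## over the core-point adjacency matrix; border points attach to the cluster
## of their nearest core neighbor within eps (same deterministic border rule
## as the implementation, but a completely different mechanism).
brute_dbscan <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  dmat <- as.matrix(dist(x))
  nb <- dmat <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  if (!any(core)) return(labels)
  ci <- which(core)
  reach <- nb[ci, ci, drop = FALSE]
  diag(reach) <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, length(ci))
  cid <- 0L
  for (i in seq_along(ci)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(reach[i, ])] <- cid
    }
  }
  labels[ci] <- comp
  for (i in which(!core)) {
    d <- dmat[i, ci]
    ok <- d <= eps
    if (any(ok)) labels[i] <- comp[which(ok)[which.min(d[ok])]]
  }
  first <- tapply(seq_len(n)[labels > 0], labels[labels > 0], min)
  remap <- integer(max(labels))
  remap[as.integer(names(first))] <- rank(first)
  labels[labels > 0] <- remap[labels[labels > 0]]
  labels
}

## Exhaustive Ward agglomeration: at every step recompute the merge cost of
## every active pair directly from the raw points (no Lance-Williams
## shortcut), merge the cheapest pair with the same smallest-id tie-break.
exhaustive_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ss <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  out <- data.table(step = integer(), a = integer(), b = integer(),
                    height = numeric())
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cost <- ss(c(members[[i]], members[[j]])) -
          ss(members[[i]]) - ss(members[[j]])
        key <- c(cost, min(ids[i], ids[j]), max(ids[i], ids[j]))
        if (is.null(best) ||
            cost < best$key[1] - 1e-12 ||
            (abs(cost - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    out <- rbind(out, data.table(step = step,
                                 a = min(ids[best$i], ids[best$j]),
                                 b = max(ids[best$i], ids[best$j]),
                                 height = best$key[1]))
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    ids[best$i] <- n + step
    members[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  out
}

## Adjusted Rand index oracle (mclust when available, else small closed form)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sij <- ch2(as.vector(tab))
  si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  n2 <- ch2(length(a))
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

## Grid-tagged standardized-ping rows for residence/activity unit tests.
fake_tagged_pings <- function(device_id, local_date, local_hour, col, row) {
  data.table(device_id = device_id, local_date = as.Date(local_date),
             local_hour = local_hour, col = as.integer(col),
             row = as.integer(row))
}
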