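# Independent brute-force oracles used to check the package's operations.
# These deliberately avoid the implementation's code paths: plain R loops,
# enumeration and closed forms only.

# flood-fill labeling by repeated breadth-first search over an R matrix;
# returns labels in first-touch scan order (column-major), as a matrix
floodFillOracle <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(rr, cc), 1)
    lab[rr, cc] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        r2 <- cur[1] + nb[k, 1]; c2 <- cur[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue <- rbind(queue, c(r2, c2))
        }
      }
    }
  }
  lab
}

# per-component (area, perimeter) from an oracle labeling; perimeter by
# counting exposed 4-neighbour edges pixel by pixel
regionStatsOracle <- function(lab) {
  ks <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- lapply(ks, function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    per <- 0L
    for (i in seq_len(nrow(px))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- px[i, 1] + d[1]; c2 <- px[i, 2] + d[2]
        if (r2 < 1 || r2 > nrow(lab) || c2 < 1 || c2 > ncol(lab) ||
            lab[r2, c2] != k)
          per <- per + 1L
      }
    }
    c(area = nrow(px), perimeter = per)
  })
  do.call(rbind, out)
}

# AUC by explicit concordance over all positive-negative pairs
aucPairsOracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# unpenalized logistic regression by Newton-Raphson with exact Hessian
newtonLogisticOracle <- function(X, y, maxit = 200, tolg = 1e-12) {
  Z <- cbind(1, X)
  th <- rep(0, ncol(Z))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(Z %*% th)
    p <- 1 / (1 + exp(-eta))
    g <- crossprod(Z, p - y) / nrow(Z)
    if (max(abs(g)) < tolg) break
    W <- p * (1 - p)
    H <- crossprod(Z * W, Z) / nrow(Z)
    th <- th - solve(H, g)
  }
  list(alpha = th[1], beta = th[-1])
}

# naive agglomerative complete linkage; returns the cophenetic matrix
# (which determines the complete-linkage ultrametric uniquely when all
# inter-cluster distances are distinct)
completeLinkCopheneticOracle <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd
    coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# exact one-sided p of the Mann-Whitney U by enumerating all group
# assignments and counting concordant pairs directly (no ranks)
uGreaterOracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  uOf <- function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    tot <- 0
    for (u in a) for (v in b) tot <- tot + (u > v) + 0.5 * (u == v)
    tot
  }
  uObs <- uOf(seq_len(n1))
  combs <- combn(length(pool), n1)
  mean(apply(combs, 2, uOf) >= uObs - 1e-9)
}

# optimal one-to-one matching under a distance cap: maximize matches,
# then minimize total distance, by exhaustive assignment enumeration
optimalMatchOracle <- function(dc, tc, maxDist) {
  nd <- nrow(dc); nt <- nrow(tc)
  D <- sqrt(outer(dc[, 1], tc[, 1], "-")^2 + outer(dc[, 2], tc[, 2], "-")^2)
  best <- list(n = -1, cost = Inf, pairs = NULL)
  assignRec <- function(i, used, pairs, cost) {
    if (i > nd) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    assignRec(i + 1, used, pairs, cost)  # leave detection i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && D[i, j] <= maxDist) {
        used[j] <- TRUE
        assignRec(i + 1, used, rbind(pairs, c(i, j)), cost + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  assignRec(1, rep(FALSE, nt), matrix(numeric(0), 0, 2), 0)
  best
}
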