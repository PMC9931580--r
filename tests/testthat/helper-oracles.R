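# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most literal formulation of each operation.

# per-pixel sorted-median with edge replication
oracle_median3x3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-1:1), 1), nr)
    jj <- pmin(pmax(j + (-1:1), 1), nc)
    out[i, j] <- median(as.vector(x[ii, jj]))
  }
  out
}

# recursive-free flood fill enumeration of connected components
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    expand.grid(di = -1:1, dj = -1:1)[-5, ]
  } else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  for (sj in seq_len(nc)) for (si in seq_len(nr)) {
    if (!mask[si, sj] || lab[si, sj] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(si, sj), 1)
    lab[si, sj] <- nxt
    while (nrow(stack)) {
      p <- stack[1, , drop = FALSE]; stack <- stack[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        ii <- p[1] + offs$di[o]; jj <- p[2] + offs$dj[o]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

# all-pairs fixed-radius edge set, rows sorted
oracle_graph <- function(x, y, radius) {
  n <- length(x)
  e <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2)
      e <- rbind(e, c(i, j))
  }
  if (is.null(e)) matrix(integer(), 0, 2) else e
}

# all-pairs sorted-distance N-nearest windows
oracle_windows <- function(x, y, types, N, type_levels) {
  n <- length(x)
  W <- matrix(0, n, length(type_levels), dimnames = list(NULL, type_levels))
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    o <- order(d, seq_len(n))[seq_len(min(N, n - 1))]
    tab <- table(factor(as.character(types)[o], levels = type_levels))
    W[i, ] <- tab / sum(tab)
  }
  W
}

# per-pixel double loop over cells and masks
oracle_majority <- function(seg, masks) {
  n <- max(seg)
  M <- matrix(0L, n, length(masks), dimnames = list(NULL, names(masks)))
  for (ci in seq_len(n)) {
    px <- which(seg == ci)
    for (k in seq_along(masks))
      M[ci, k] <- sum(masks[[k]][px])
  }
  M
}

# textbook two-group log-rank: O-E over distinct event times
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# mean silhouette for a 2-group labelling on 2-D points
oracle_silhouette <- function(Y, lab) {
  n <- nrow(Y)
  D <- as.matrix(dist(Y))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(tapply(D[i, !(lab == lab[i])], lab[!(lab == lab[i])], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small standard simulation config shared across tests
test_config <- function(...) {
  sim_config(width = 300L, height = 300L, n_cells = 250L,
             proportions = c(Tumour = 0.4, Macrophage = 0.3,
                             Endothelial = 0.2, Undefined = 0.1), ...)
}
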