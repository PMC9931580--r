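#' @useDynLib imcniche, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov dist kmeans median p.adjust pchisq quantile rexp
#'   rlnorm rnorm rpois runif sd shapiro.test t.test wilcox.test TukeyHSD
#'   rbinom fisher.test complete.cases setNames var
#' @importFrom utils read.csv write.csv head
NULL

#' Derive a reproducible stream seed from a master seed
#'
#' Hashes the master seed together with an arbitrary set of string/numeric
#' tags into an integer in `[0, 2^31 - 2]`. Used throughout the package so
#' that every stochastic stage draws from its own deterministic stream,
#' making results independent of execution order.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the stream, e.g. an
#'   image id and a stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                       character(1)), collapse = "|")
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  bytes <- utf8ToInt(tags)
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# k-means++ seeding on rows of X (matrix n x d). Returns row indices.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  if (k >= 2) {
    for (j in 2:k) {
      tot <- sum(d2)
      if (tot <= 0) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2 / tot)
      }
      nd2 <- rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  idx
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 means identical partitions up to relabelling, 0 is the expectation
#' under independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

# squared Euclidean cross-distances between rows of A (n x d) and B (m x d)
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
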