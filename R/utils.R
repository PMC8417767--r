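#' @importFrom stats rnorm runif sd integrate setNames rgamma
#' @importFrom utils head tail modifyList
NULL

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(x) sqrt(rowSums(x * x))

# Normalize rows to unit length; errors on (near-)zero rows unless `label` is NULL.
normalize_rows <- function(x, label = "vector", tol = 1e-12) {
  n <- row_norms(x)
  bad <- which(n < tol)
  if (length(bad) && !is.null(label)) {
    stop(sprintf("cannot normalize zero %s at index %d", label, bad[1]), call. = FALSE)
  }
  x / pmax(n, tol)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Derive a reproducible stage seed from a master seed
#'
#' Fans a single master seed out to per-stage seeds by stable string hashing,
#' so that independent pipeline stages (fixture generation, noise, cone
#' azimuths, ...) use decorrelated but fully reproducible random streams.
#'
#' @param master Integer master seed.
#' @param ... Character/numeric labels identifying the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- as.numeric(master) %% 2147483629
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

# Rotation matrix for angle `theta` (radians) about unit axis `ax` (Rodrigues).
rotation_matrix <- function(ax, theta) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
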