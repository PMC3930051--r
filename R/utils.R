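#' @importFrom rlang %||% abort warn
#' @importFrom stats cor sd var rbeta rbinom rnorm runif quantile optimize
#'   pchisq pnorm pt setNames complete.cases
NULL

# lower-triangle unfolding used everywhere distances become vectors;
# column-major order: (2,1),(3,1),...,(n,1),(3,2),...
unfold_lower <- function(m) m[lower.tri(m)]

fold_lower <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

# pair index table matching unfold_lower() order
pair_index <- function(labels) {
  n <- length(labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    pop1 = labels[idx[, 1]], pop2 = labels[idx[, 2]]
  )
}

check_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0("`", name, "` must be a square matrix"))
  }
  invisible(m)
}

# deterministic sub-seeds so each generator stage draws from its own stream
# while the whole dataset stays reproducible from one integer
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 99991 * offset) %% 2147483399) + 1L
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
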