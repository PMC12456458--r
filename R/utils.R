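## Small internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic arithmetic spawning so that each (setting, repetition) pair of
#' a simulation grid gets an independent, reproducible seed below 2^31.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (setting index, rep index, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 2654435761 + k) %% 2147483629
  }
  as.integer(s) + 1L
}

## All permutations of 1..n as rows of a matrix (n! x n), lexicographic order.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

l1 <- function(x) sum(abs(x))

## Index of the largest-magnitude component; ties broken toward the lowest index.
which_max_abs <- function(x) which.max(abs(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_clusso <- function(...) stop(sprintf(...), call. = FALSE)
warn_clusso <- function(...) warning(sprintf(...), call. = FALSE)
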