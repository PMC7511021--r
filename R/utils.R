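`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar numeric check with domain constraints
.chk_num <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop(sprintf("'%s' = %g outside the admissible interval [%g, %g]",
                 name, x, lower, upper), call. = FALSE)
  }
  as.numeric(x)
}

.stop_class <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# order-sensitive 32-bit rolling hash of a character scalar (run metadata)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

.relerr <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, 0, d / s)
}
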