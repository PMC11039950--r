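`%||%` <- function(x, y) if (is.null(x)) y else x

# 95% two-sided normal quantile used for all confidence intervals
.z95 <- qnorm(0.975)

mrb_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mrbiome_error", "error", "condition")))
}

stop_format <- function(msg) mrb_error(msg, "mrbiome_format_error")
stop_usage <- function(msg) mrb_error(msg, "mrbiome_usage_error")

stop_insufficient <- function(method, need, have) {
  mrb_error(
    sprintf("%s requires at least %d instruments, got %d", method, need, have),
    "mrbiome_insufficient_error"
  )
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded estimators do not perturb outer simulations.
# seed = NULL means "use the current RNG stream".
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

is_probability <- function(p) is.numeric(p) & is.finite(p) & p > 0 & p <= 1

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_usage(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
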