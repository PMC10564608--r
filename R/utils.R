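# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Run an expression under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.", class = "nova24r_contract_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Proportional split of a mass that conserves the total exactly: the last
# share absorbs the floating-point remainder.
split_exact <- function(total, fractions) {
  stopifnot(length(fractions) >= 1L, all(fractions > 0))
  out <- total * fractions
  out[length(out)] <- total - sum(out[-length(out)])
  out
}

# Stop with a classed condition so callers can distinguish contract violations,
# integrity failures and state errors.
nova_abort <- function(message, class) {
  abort(message, class = c(class, "nova24r_error"))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Atomic write: render to a temp file in the destination directory, then rename.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
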