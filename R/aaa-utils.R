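#' @keywords internal
"_PACKAGE"

## Error raised for bad user input (file problems, invalid arguments coming
## from the command line). The CLI maps it to exit code 1; everything else
## is an internal error (exit code 2).
stop_user <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("sc3kit_user_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## set.seed scoped to a block; restores (or removes) .Random.seed afterwards
## so generators are deterministic without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
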