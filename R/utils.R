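# internal helpers shared across modules

MONTH_DAYS <- 30.4375   # mean Gregorian month; cycle lengths in days -> months
STATES <- c("pfs", "rfs", "pd", "dead")

abort_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(structure(
    class = c("haiccea_validation_error", "haiccea_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_model <- function(msg) {
  stop(structure(
    class = c("haiccea_model_error", "haiccea_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x))
    abort_validation("missing or non-numeric parameter", field)
  if (x < min || x > max)
    abort_validation(sprintf("value %g outside [%g, %g]", x, min, max), field)
  invisible(TRUE)
}

check_probability <- function(x, field) check_number(x, field, 0, 1)

# nested list access by character path
pluck_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

poke_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
    return(x)
  }
  x[[path[1L]]] <- poke_path(x[[path[1L]]], path[-1L], value)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
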