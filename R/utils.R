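## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so callers/tests can distinguish usage, parse, key and
## validation failures (the CLI maps these to exit codes).
pt_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("predtopics_", class, "_error"), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pt_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Deterministic child seeds: every stochastic routine derives its streams from
## one user-facing integer seed.  Keep results < 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

## Escape a string for inclusion in XML attribute/text content.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

## Lexicographic sort that does not depend on the session locale.
lex_sort <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

lex_order <- function(...) order(..., method = "radix")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
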