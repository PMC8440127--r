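# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's RNG state, so
#' seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# The 26 single-letter COG functional categories, in the canonical order,
# plus the label used for clusters without an assignment.
cog_alphabet <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W",
    "U", "O", "X", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

cog_levels <- function() c(cog_alphabet(), "Not_assigned")

oxygen_classes <- function() {
  c("microaerobic", "facultatively_anaerobic", "obligate_anaerobic")
}

# deterministic TSV writer used by every stage
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", na.strings = NULL,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
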