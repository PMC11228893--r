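#' @importFrom stats coef complete.cases cor.test lm glm binomial median na.omit
#'   p.adjust pnorm prcomp qchisq qlogis qnorm qt quantile rbinom rnorm rpois
#'   runif sd setNames wilcox.test confint vcov predict plogis
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom methods is
#' @importFrom graphics hist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ribocn <- function(..., class = "ribocn_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "ribocn_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ribocn(name, " must be a single finite number")
  if (positive && x <= 0) stop_ribocn(name, " must be > 0")
  if (nonneg && x < 0) stop_ribocn(name, " must be >= 0")
  invisible(x)
}

#' Write a tab-separated table with a provenance header
#'
#' Tables are UTF-8, tab-separated, with a mandatory header row and missing
#' values encoded as empty fields. A comment line records the package version
#' so outputs are traceable.
#'
#' @param x data.frame to write.
#' @param path destination file.
#' @param provenance logical; prepend a `#` provenance comment line.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = TRUE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (provenance)
    writeLines(sprintf("# ribocn %s", as.character(packageVersion("ribocn"))), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file to read.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_ribocn("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             na.strings = "", stringsAsFactors = FALSE, check.names = FALSE)
}
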