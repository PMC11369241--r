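#' @importFrom data.table data.table := setorder rbindlist setnames setattr setcolorder as.data.table .N .SD .I fifelse
#' @importFrom stats dbinom dpois median rbinom rlnorm runif setNames na.omit
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Extract characters at positions of a single string (vectorised over pos)
#' @noRd
chars_at <- function(x, pos) {
  substring(x, pos, pos)
}

# mean of a lognormal with target mean m and sd s -> (meanlog, sdlog)
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x)) stop(name, " must be a non-missing scalar")
  invisible(x)
}
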