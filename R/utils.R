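# Internal helpers shared across modules.

VAR_TYPES <- c("SNP", "MNP", "insertion", "deletion")
DYES <- c("FAM", "VIC", "PET", "none")
CONTINENTS <- c("Asia", "Europe", "NorthAmerica")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_oak <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oakorigin_error")))
}

is_dna <- function(x, allow_n = TRUE, allow_gap = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (allow_gap) alphabet <- paste0(alphabet, "-")
  !grepl(sprintf("[^%s]", alphabet), x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# scalar integer check for user-facing parameters
check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_oak(sprintf("'%s' must be a single integer >= %d", name, min),
              "oakorigin_parameter_error")
  }
  as.integer(x)
}

#' @keywords internal
#' @importFrom stats setNames rnbinom rbinom rpois runif qbeta
#' @importFrom utils read.csv write.csv
"_PACKAGE"
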