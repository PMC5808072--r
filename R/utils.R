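#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbinom rnbinom rpois rhyper runif p.adjust
#'   poisson.test setNames
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under `seed` when seed is given, leaving the global RNG state
# untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  assert_that(x >= lower && x <= upper,
              sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

assert_dna <- function(seq, name = "seq") {
  assert_that(is.character(seq) && length(seq) == 1L && nchar(seq) >= 1L,
              sprintf("`%s` must be a non-empty character scalar", name))
  bad <- gsub("[ACGT]", "", toupper(seq))
  assert_that(nchar(bad) == 0L,
              sprintf("`%s` contains non-ACGT characters: '%s'", name,
                      substr(bad, 1L, 10L)))
  invisible(toupper(seq))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Stable hash of a configuration list: md5 of its canonical JSON serialisation.
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config = NULL, seed = NULL) {
  h <- sprintf("# lamingate v%s", as.character(utils::packageVersion("lamingate")))
  if (!is.null(config)) h <- c(h, sprintf("# config_hash=%s", config_hash(config)))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%d", as.integer(seed)))
  h
}
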