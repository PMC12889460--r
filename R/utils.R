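# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All user-facing randomness goes
# through this, so a seed argument fully determines a function's output
# without disturbing the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

# sample() interprets a length-1 numeric x as 1:x; this always samples
# from the elements of x.
sample_one <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

variant_key_cols <- c("chrom", "pos", "ref", "alt")

variant_key <- function(tab) {
  paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
}

# Columns of a variant table that hold scores: everything except the
# structural columns.
score_columns <- function(tab) {
  setdiff(names(tab), c(variant_key_cols, "gene", "aaref", "aaalt"))
}

check_variant_table <- function(tab) {
  missing <- setdiff(c(variant_key_cols, "gene"), names(tab))
  if (length(missing) > 0L) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

check_codes <- function(codes) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(0L, 1L, 2L))) {
    stop("invalid observation code: entries must be 0, 1 or 2", call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  codes
}
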