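#' Read and write variant score tables
#'
#' Tab-separated with a header; required columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `gene`; optional `aaref`, `aaalt`; every remaining column
#' is treated as a numeric score.  `"."` or an empty cell means missing.
#' Row order is preserved; a non-numeric score cell is an error naming the
#' row.
#'
#' @param path file path.
#' @return A variant table data frame.
#' @export
read_variant_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
  check_variant_table(tab)
  tab$pos <- as.integer(tab$pos)
  for (sc in score_columns(tab)) {
    raw <- tab[[sc]]
    raw[raw == "." | raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric value in score column '", sc, "' at row ", bad[1L])
    }
    tab[[sc]] <- num
  }
  tab
}

#' @param table a variant table.
#' @rdname read_variant_table
#' @export
write_variant_table <- function(table, path) {
  out <- table
  for (sc in score_columns(out)) {
    v <- format(out[[sc]], trim = TRUE, digits = 15)
    v[is.na(out[[sc]])] <- "."
    out[[sc]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' 0-based half-open intervals; validated (`start < end`, with the
#' offending line number reported) and returned per-chromosome sorted.
#'
#' @param path file path.
#' @return Data frame with `chrom`, `start`, `end` (plus `name` if a
#'   fourth column is present).
#' @export
read_bed <- function(path) {
  bed <- read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4L) names(bed)[4L] <- "name"
  bad <- which(bed$start >= bed$end)
  if (length(bad) > 0L) {
    stop("malformed interval (start >= end) at line ", bad[1L])
  }
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  rownames(bed) <- NULL
  bed
}

#' Write state assignments as TSV or BED
#'
#' The TSV carries `chrom`, `pos` (1-based), `ref`, `alt`, `gene`,
#' `state` (plus voting diagnostics when present).  The BED export writes
#' 0-based half-open single-nucleotide intervals with the state in the
#' name field.
#'
#' @param assignments an assignment data frame or [annotate_variants()]
#'   result.
#' @param path file path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_assignments <- function(assignments, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  a <- as_assignments(assignments)
  if (format == "tsv") {
    write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = a$chrom, start = a$pos - 1L, end = a$pos,
                      name = paste0("state_", a$state))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read state assignments written by [write_assignments()]
#'
#' @param path file path.
#' @return An assignment data frame.
#' @export
read_assignments <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, quote = "")
  a$pos <- as.integer(a$pos)
  a$state <- as.integer(a$state)
  a
}

#' Write and read per-gene ternary code files
#'
#' One tab-separated file per gene (named `<gene>_codes.tsv`, header =
#' score names, one row per position), mirroring the per-gene training
#' unit structure, plus a `manifest.tsv` mapping each sequence position to
#' its chosen variant row.
#'
#' @param sequences a `variant_sequences` object
#'   (from [build_training_sequences()]).
#' @param dir output directory (created if needed).
#' @return `write_code_files` returns `dir` invisibly; `read_code_files`
#'   returns a `variant_sequences` object (with a manifest if present).
#' @export
write_code_files <- function(sequences, dir) {
  stopifnot(inherits(sequences, "variant_sequences"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(sequences$codes)) {
    write.table(sequences$codes[[g]],
                file.path(dir, paste0(g, "_codes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sequences$manifest)) {
    write.table(sequences$manifest, file.path(dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_code_files
#' @export
read_code_files <- function(dir) {
  files <- sort(list.files(dir, pattern = "_codes\\.tsv$"))
  if (length(files) == 0L) stop("no code files found in ", dir)
  codes <- lapply(files, function(f) {
    m <- as.matrix(read.table(file.path(dir, f), header = TRUE, sep = "\t",
                              check.names = FALSE))
    storage.mode(m) <- "integer"
    m
  })
  names(codes) <- sub("_codes\\.tsv$", "", files)
  manifest_path <- file.path(dir, "manifest.tsv")
  manifest <- if (file.exists(manifest_path)) {
    read.table(manifest_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  }
  structure(list(codes = codes, manifest = manifest),
            class = "variant_sequences")
}
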