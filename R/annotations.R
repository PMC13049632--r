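#' Read an intron annotation table
#'
#' Loads a tab-separated intron inventory with minor/major classification,
#' emulating exports from a minor-intron database. Coordinates are stored
#' 0-based half-open (BED convention); a `bed6` reader flag accepts BED6+
#' column ordering (chrom, start, end, name, score, strand) with `gene_id`
#' and `intron_class` in columns 7 and 8.
#'
#' @param path Path to a TSV with header columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `intron_class` (and optional `subtype`, the
#'   terminal-dinucleotide tag such as `AT-AC`).
#' @param bed6 Logical; if `TRUE` the file is headerless BED6+2.
#' @return A tibble intron registry, one row per unique
#'   (chrom, start, end, strand) key, validated by [intron_registry()].
#' @export
read_intron_annotations <- function(path, bed6 = FALSE) {
  if (bed6) {
    raw <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "name", "score", "strand",
                    "gene_id", "intron_class"),
      col_types = readr::cols(
        chrom = "c", start = "d", end = "d", name = "c", score = "c",
        strand = "c", gene_id = "c", intron_class = "c"
      ),
      progress = FALSE
    )
    raw <- dplyr::select(raw, -"name", -"score")
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  }
  intron_registry(raw)
}

#' Validate an intron registry
#'
#' Checks a data frame of intron records: `end > start`, `intron_class`
#' in `minor`/`major`, unique (chrom, start, end, strand) keys. Duplicate
#' keys with identical class are collapsed with a warning; conflicting
#' classes on the same key are an error.
#'
#' @param introns Data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `intron_class` (optional `subtype`).
#' @return A validated tibble with a `mirout_tally` attribute giving
#'   minor/major record counts.
#' @export
intron_registry <- function(introns) {
  introns <- as_tibble(introns)
  required <- c("chrom", "start", "end", "strand", "gene_id", "intron_class")
  missing_cols <- setdiff(required, names(introns))
  if (length(missing_cols) > 0) {
    abort(paste0("intron table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(introns$start) || !is.numeric(introns$end)) {
    abort("intron coordinates must be numeric")
  }
  bad_len <- which(introns$end <= introns$start)
  if (length(bad_len) > 0) {
    abort(paste0("zero-length intron at line ", bad_len[1],
                 " (end <= start)"))
  }
  bad_class <- which(!introns$intron_class %in% c("minor", "major"))
  if (length(bad_class) > 0) {
    abort(paste0("unknown intron_class '",
                 introns$intron_class[bad_class[1]],
                 "' at line ", bad_class[1]))
  }
  bad_strand <- which(!introns$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand at line ", bad_strand[1]))
  }
  key <- intron_key(introns)
  if (anyDuplicated(key)) {
    n_class <- tapply(introns$intron_class, key, function(x) length(unique(x)))
    if (any(n_class > 1)) {
      abort("duplicate intron key with conflicting intron_class")
    }
    warn(paste0(sum(duplicated(key)),
                " duplicate intron record(s) collapsed"))
    introns <- introns[!duplicated(key), , drop = FALSE]
  }
  attr(introns, "mirout_tally") <- c(
    minor = sum(introns$intron_class == "minor"),
    major = sum(introns$intron_class == "major")
  )
  introns
}

#' Write an intron registry to TSV
#'
#' @param introns Intron registry tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intron_annotations <- function(introns, path) {
  readr::write_tsv(as_tibble(introns), path, progress = FALSE)
  invisible(path)
}

# Canonical string key used for exact-match intron intersection.
intron_key <- function(x) {
  paste0(x$chrom, ":", format(x$start, scientific = FALSE, trim = TRUE), "-",
         format(x$end, scientific = FALSE, trim = TRUE), ":", x$strand)
}

#' Restrict outlier calls to minor introns
#'
#' Keeps exactly the calls whose (chrom, start, end, strand) key matches a
#' registry record classified as minor. Matching is exact-key, not overlap:
#' calls and annotations are assumed to derive from the same intron
#' inventory. Calls at introns absent from the registry are dropped and
#' tallied as unannotated rather than raising an error.
#'
#' @param calls Tibble of outlier calls carrying `chrom`, `start`, `end`,
#'   `strand` columns (e.g. from [call_outliers()]).
#' @param introns Intron registry from [intron_registry()].
#' @return The minor-intron subset of `calls`, input order preserved, with
#'   attribute `mirout_tally` = counts of minor-matched, major-matched and
#'   unannotated calls.
#' @export
restrict_to_minor <- function(calls, introns) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    out <- calls
    attr(out, "mirout_tally") <- c(minor = 0L, major = 0L, unannotated = 0L)
    return(out)
  }
  ckey <- intron_key(calls)
  rkey <- intron_key(introns)
  cls <- introns$intron_class[match(ckey, rkey)]
  out <- calls[!is.na(cls) & cls == "minor", , drop = FALSE]
  attr(out, "mirout_tally") <- c(
    minor = sum(cls == "minor", na.rm = TRUE),
    major = sum(cls == "major", na.rm = TRUE),
    unannotated = sum(is.na(cls))
  )
  out
}

#' Look up the gene class of calls
#'
#' Convenience join of registry columns (`gene_id`, `intron_class`,
#' optionally `subtype`) onto a call table by exact intron key.
#'
#' @inheritParams restrict_to_minor
#' @return `calls` with `gene_id` and `intron_class` columns added
#'   (`NA` where unannotated).
#' @export
annotate_calls <- function(calls, introns) {
  calls <- as_tibble(calls)
  ckey <- intron_key(calls)
  idx <- match(ckey, intron_key(introns))
  calls$gene_id <- introns$gene_id[idx]
  calls$intron_class <- introns$intron_class[idx]
  calls
}
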