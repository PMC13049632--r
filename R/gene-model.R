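#' Construct an snRNA gene model
#'
#' An snRNA gene model anchors HGVS n. coordinate conversion and structural
#' annotation for a short non-coding RNA gene: the 1-based inclusive genomic
#' span, strand, named structural regions in snRNA (n.) coordinates, and
#' duplex base-pairing registers against a partner snRNA (e.g. the
#' U4atac/U6atac stem I and II bimolecule helices).
#'
#' @param name Gene symbol (e.g. `"RNU6ATAC"`).
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive genomic span; gene length is
#'   `end - start + 1`.
#' @param strand `"+"` or `"-"`. On the minus strand n.1 anchors at `end`.
#' @param regions Data frame with columns `label`, `n_start`, `n_end`
#'   (1-based snRNA coordinates, inclusive). May be `NULL`.
#' @param registers Data frame of duplex registers with columns `partner`,
#'   `own_start`, `own_end`, `partner_start`, `partner_end`, and optional
#'   `orientation` (only `"antiparallel"` is supported: helices pair the
#'   i-th own position with the i-th position of the reversed partner
#'   range). May be `NULL`.
#' @return An object of class `snrna_gene_model`.
#' @export
snrna_gene_model <- function(name, chrom, start, end, strand,
                             regions = NULL, registers = NULL) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (end < start) abort("gene end precedes start")
  len <- end - start + 1
  regions <- if (is.null(regions)) {
    tibble(label = character(), n_start = integer(), n_end = integer())
  } else {
    as_tibble(regions)
  }
  if (nrow(regions) > 0) {
    if (any(regions$n_start > regions$n_end)) {
      bad <- regions$label[which(regions$n_start > regions$n_end)[1]]
      abort(paste0("inverted region '", bad, "' (n_start > n_end)"))
    }
    if (any(regions$n_start < 1) || any(regions$n_end > len)) {
      abort("region outside [1, gene length]")
    }
    if (anyDuplicated(regions$label)) abort("region labels must be unique")
    ov <- .regions_overlap(regions)
    if (ov) inform("gene model has overlapping regions; first match wins")
  }
  registers <- if (is.null(registers)) {
    tibble(partner = character(), own_start = integer(), own_end = integer(),
           partner_start = integer(), partner_end = integer())
  } else {
    as_tibble(registers)
  }
  if (nrow(registers) > 0) {
    if ("orientation" %in% names(registers) &&
        any(registers$orientation != "antiparallel")) {
      abort("only antiparallel duplex registers are supported")
    }
    own_len <- registers$own_end - registers$own_start + 1
    par_len <- registers$partner_end - registers$partner_start + 1
    if (any(own_len != par_len)) {
      abort("duplex register ranges differ in length")
    }
    if (any(own_len < 1)) abort("inverted duplex register range")
    if (any(registers$own_start < 1) || any(registers$own_end > len)) {
      abort("duplex register outside [1, gene length]")
    }
  }
  structure(
    list(name = name, chrom = chrom, start = start, end = end,
         strand = strand, length = len,
         regions = regions, registers = registers),
    class = "snrna_gene_model"
  )
}

.regions_overlap <- function(regions) {
  if (nrow(regions) < 2) return(FALSE)
  r <- regions[order(regions$n_start), ]
  any(r$n_start[-1] <= r$n_end[-nrow(r)])
}

#' Load an snRNA gene model from a YAML config
#'
#' The config is a human-editable key-value file; see the `rnu6atac.yaml`
#' fixture under `inst/extdata` for the schema:
#' top-level `name`, `chrom`, `start`, `end`, `strand`, then `regions:` as a
#' list of `{label, n_start, n_end}` and `registers:` as a list of
#' `{partner, own_start, own_end, partner_start, partner_end, orientation}`.
#'
#' @param path Path to a YAML gene-model file.
#' @return An `snrna_gene_model`.
#' @export
read_gene_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("name", "chrom", "start", "end", "strand")) {
    if (is.null(cfg[[f]])) abort(paste0("gene model config lacks '", f, "'"))
  }
  to_tbl <- function(x) {
    if (is.null(x) || length(x) == 0) NULL else dplyr::bind_rows(x)
  }
  snrna_gene_model(
    name = cfg$name, chrom = as.character(cfg$chrom),
    start = as.numeric(cfg$start), end = as.numeric(cfg$end),
    strand = cfg$strand,
    regions = to_tbl(cfg$regions),
    registers = to_tbl(cfg$registers)
  )
}

#' @method print snrna_gene_model
#' @export
print.snrna_gene_model <- function(x, ...) {
  cat("<snrna_gene_model> ", x$name, "\n",
      "  ", x$chrom, ":", format(x$start, big.mark = ","), "-",
      format(x$end, big.mark = ","), " (", x$strand, "), length ",
      x$length, " nt\n",
      "  ", nrow(x$regions), " structural region(s), ",
      nrow(x$registers), " duplex register(s)\n", sep = "")
  invisible(x)
}

#' Bundled RNU6ATAC gene model
#'
#' Convenience loader for the shipped U6atac snRNA gene model
#' (GRCh38 chr9:134,164,439-134,164,564, minus strand, 126 nt) with the
#' U4atac/U6atac stem I, stem I/II boundary, stem II and central stem-loop
#' regions and the stem duplex registers against U4atac. Region boundaries
#' beyond the positions validated by published variant annotations are
#' editable configuration, seeded from secondary-structure models.
#'
#' @return An `snrna_gene_model`.
#' @export
rnu6atac_model <- function() {
  read_gene_model(system.file("extdata", "rnu6atac.yaml",
                              package = "mirout", mustWork = TRUE))
}
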