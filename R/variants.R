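COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_base <- function(x) {
  out <- unname(COMPLEMENT[toupper(x)])
  if (anyNA(out)) abort("alleles must be single bases A/C/G/T")
  out
}

#' Convert genomic SNVs to snRNA (HGVS n.) coordinates
#'
#' Maps 1-based genomic positions inside an snRNA gene span onto the RNA
#' sense strand: on the plus strand `n = pos - start + 1` with alleles
#' unchanged; on the minus strand `n = end - pos + 1` with alleles
#' reverse-complemented (single bases, so complemented). The HGVS n.
#' string is `n.<pos><REF>><ALT>` in snRNA sense.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` (single-base
#'   SNV alleles).
#' @param model An [snrna_gene_model()].
#' @return `variants` with `n_pos`, `ref_n`, `alt_n` and `hgvs_n` added.
#' @export
genomic_to_snrna <- function(variants, model) {
  variants <- as_tibble(variants)
  if (any(nchar(variants$ref) != 1 | nchar(variants$alt) != 1)) {
    abort("SNV only: ref and alt must be single bases")
  }
  if (any(variants$ref == variants$alt)) abort("ref and alt must differ")
  outside <- variants$pos < model$start | variants$pos > model$end |
    variants$chrom != model$chrom
  if (any(outside)) {
    abort(paste0("variant at ", variants$chrom[outside][1], ":",
                 variants$pos[outside][1], " is outside gene ", model$name))
  }
  if (model$strand == "-") {
    n_pos <- model$end - variants$pos + 1
    ref_n <- complement_base(variants$ref)
    alt_n <- complement_base(variants$alt)
  } else {
    n_pos <- variants$pos - model$start + 1
    ref_n <- toupper(variants$ref)
    alt_n <- toupper(variants$alt)
  }
  variants %>%
    mutate(
      n_pos = n_pos,
      ref_n = ref_n,
      alt_n = alt_n,
      hgvs_n = paste0("n.", n_pos, ref_n, ">", alt_n)
    )
}

#' Convert snRNA coordinates back to genomic
#'
#' Inverse of [genomic_to_snrna()]: snRNA position and sense-strand
#' alleles to genomic position and alleles.
#'
#' @param n_pos snRNA position(s), 1-based.
#' @param ref_n,alt_n snRNA sense-strand alleles.
#' @param model An [snrna_gene_model()].
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @export
snrna_to_genomic <- function(n_pos, ref_n, alt_n, model) {
  if (any(n_pos < 1 | n_pos > model$length)) {
    abort("n_pos outside [1, gene length]")
  }
  if (model$strand == "-") {
    pos <- model$end - n_pos + 1
    ref <- complement_base(ref_n)
    alt <- complement_base(alt_n)
  } else {
    pos <- model$start + n_pos - 1
    ref <- toupper(ref_n)
    alt <- toupper(alt_n)
  }
  tibble(chrom = model$chrom, pos = pos, ref = ref, alt = alt)
}

#' Annotate snRNA structural region and duplex pairing partner
#'
#' Looks up the first configured structural region containing each snRNA
#' position (label `"unassigned"` when none matches) and, when the
#' position lies inside a duplex register, the base-pairing partner: in an
#' antiparallel helix the i-th position of the own range pairs with the
#' i-th position of the reversed partner range.
#'
#' @param n_pos snRNA position(s), 1-based.
#' @param model An [snrna_gene_model()].
#' @return Tibble (`n_pos`, `region_label`, `partner_gene`,
#'   `partner_pos`); partner columns `NA` outside any register.
#' @export
annotate_structure <- function(n_pos, model) {
  if (any(n_pos < 1 | n_pos > model$length)) {
    abort("n_pos outside [1, gene length]")
  }
  regions <- model$regions
  registers <- model$registers
  one <- function(np) {
    label <- "unassigned"
    if (nrow(regions) > 0) {
      hit <- which(regions$n_start <= np & np <= regions$n_end)
      if (length(hit) > 0) label <- regions$label[hit[1]]
    }
    pg <- NA_character_; pp <- NA_real_
    if (nrow(registers) > 0) {
      hit <- which(registers$own_start <= np & np <= registers$own_end)
      if (length(hit) > 0) {
        reg <- registers[hit[1], ]
        pg <- reg$partner
        pp <- reg$partner_end - (np - reg$own_start)
      }
    }
    tibble(n_pos = np, region_label = label,
           partner_gene = pg, partner_pos = pp)
  }
  dplyr::bind_rows(lapply(n_pos, one))
}

#' Read snRNA-region variants from a VCF
#'
#' Parses a VCF 4.x (1-based, SNVs and others; multi-allelic records are
#' split) and pulls `AF`, `CADD` and `PHYLOP` from INFO when present. A
#' side annotation table keyed by chrom-pos-ref-alt can supply or override
#' these scores; computation of the scores themselves is out of scope.
#'
#' @param path VCF path.
#' @param annotations Optional data frame with `chrom`, `pos`, `ref`,
#'   `alt` and any of `af`, `cadd`, `phylop`.
#' @return Tibble (`chrom`, `pos`, `ref`, `alt`, `af`, `cadd`, `phylop`,
#'   `inheritance` when an `INH` INFO field is present).
#' @export
read_snrna_variants <- function(path, annotations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_num <- function(field) {
    v <- vcfR::extract.info(vcf, element = field)
    if (is.null(v)) return(rep(NA_real_, nrow(fix)))
    suppressWarnings(as.numeric(v))
  }
  info_chr <- function(field) {
    v <- vcfR::extract.info(vcf, element = field)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else as.character(v)
  }
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    af = info_num("AF"),
    cadd = info_num("CADD"),
    phylop = info_num("PHYLOP"),
    inheritance = info_chr("INH")
  ) %>%
    tidyr::separate_rows("alt", sep = ",")
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations)
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "-")
    idx <- match(key(out), key(ann))
    for (f in intersect(c("af", "cadd", "phylop"), names(ann))) {
      hit <- !is.na(idx) & !is.na(ann[[f]][idx])
      out[[f]][hit] <- ann[[f]][idx][hit]
    }
  }
  out
}

#' Prioritize snRNA variants by frequency and deleteriousness
#'
#' Applies the rare-variant prioritization used for minor spliceosome
#' snRNA genes: keep variants inside the gene span with population allele
#' frequency below `af_max` (absent AF is treated as 0 and retained) and a
#' CADD Phred score at or above the region-aware non-coding threshold
#' `cadd_min` (default 11.44). Every input is returned annotated with
#' snRNA coordinates, structural region, duplex partner, a `passed` flag
#' and the list of failed conditions; this is a filter, not a validator.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and optional
#'   `af`, `cadd`, `phylop`, `inheritance`.
#' @param model An [snrna_gene_model()].
#' @param af_max Maximum allele frequency (default 0.01, i.e. AF < 1%).
#' @param cadd_min Minimum CADD Phred score (default 11.44).
#' @return Annotated tibble with `n_pos`, `hgvs_n`, `region_label`,
#'   `partner_gene`, `partner_pos`, `passed`, `fail_reasons`
#'   (comma-separated, empty when passed).
#' @export
apply_prioritization <- function(variants, model, af_max = 0.01,
                                 cadd_min = 11.44) {
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, n_pos = numeric(), hgvs_n = character(),
                  region_label = character(), partner_gene = character(),
                  partner_pos = numeric(), passed = logical(),
                  fail_reasons = character()))
  }
  if (!"af" %in% names(variants)) variants$af <- NA_real_
  if (!"cadd" %in% names(variants)) variants$cadd <- NA_real_
  in_gene <- variants$chrom == model$chrom &
    variants$pos >= model$start & variants$pos <= model$end
  af_eff <- if_else(is.na(variants$af), 0, variants$af)
  af_ok <- af_eff < af_max
  cadd_ok <- !is.na(variants$cadd) & variants$cadd >= cadd_min

  ann <- variants
  ann$n_pos <- NA_real_
  ann$hgvs_n <- NA_character_
  ann$region_label <- NA_character_
  ann$partner_gene <- NA_character_
  ann$partner_pos <- NA_real_
  if (any(in_gene)) {
    conv <- genomic_to_snrna(variants[in_gene, ], model)
    struct <- annotate_structure(conv$n_pos, model)
    ann$n_pos[in_gene] <- conv$n_pos
    ann$hgvs_n[in_gene] <- conv$hgvs_n
    ann$region_label[in_gene] <- struct$region_label
    ann$partner_gene[in_gene] <- struct$partner_gene
    ann$partner_pos[in_gene] <- struct$partner_pos
  }
  reasons <- purrr::pmap_chr(
    list(in_gene, af_ok, cadd_ok),
    function(g, a, c) {
      paste(c(if (!g) "outside_gene", if (!a) "af", if (!c) "cadd"),
            collapse = ",")
    }
  )
  ann %>%
    mutate(
      passed = in_gene & af_ok & cadd_ok,
      fail_reasons = reasons
    )
}
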