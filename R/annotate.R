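## Region-aware annotation of variants within miRNA hairpins.
##
## Region classes partition each hairpin: the seed (bases 2-8 from the 5' end
## of a mature arm), the rest of the mature arm, and the remaining stem-loop
## bases. Precedence for multi-base variants is seed > mature > stem-loop.

#' Seed interval of a mature miRNA arm
#'
#' The seed is bases 2-8 counted from the 5' end of the mature strand. On the
#' plus strand the 5' end is the lower genomic coordinate; on the minus strand
#' it is the higher one, and counting walks downward.
#'
#' @param mature_interval integer vector `c(start, end)`, 1-based closed
#' @param strand `"+"` or `"-"`
#' @return integer `c(start, end)` of the 7-base seed, 1-based closed
#' @export
#' @examples
#' seed_interval(c(100, 121), "+")  # 101..107
#' seed_interval(c(100, 121), "-")  # 114..120
seed_interval <- function(mature_interval, strand) {
  s <- mature_interval[1]; e <- mature_interval[2]
  len <- e - s + 1L
  if (len < 8L) stop("mature arm of length ", len, " is too short for a seed (< 8 nt)")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "+") c(s + 1L, s + 7L) else c(e - 7L, e - 1L)
}

catalog_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

variant_granges <- function(variants) {
  # a variant occupies [pos, pos + nchar(ref) - 1]: a SNP one base, a deletion
  # its deleted span; an insertion sits at its anchor base
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos,
                                          variants$pos + nchar(variants$ref) - 1L))
}

#' Classify variants into seed / mature / stem-loop regions
#'
#' A variant overlapping a seed interval is `seed`; otherwise overlapping a
#' mature arm is `mature`; otherwise inside a hairpin is `stem-loop`; otherwise
#' `none`. For multi-base variants any overlap with the higher-precedence
#' region wins. A variant hit by two overlapping hairpins yields one annotated
#' record per hairpin (distinct `mirna_id`).
#'
#' @param vt a [variant_table()]
#' @param catalog a [mirna_catalog()]
#' @return data.frame with one row per (variant record, hairpin) pair —
#'   columns of `vt$variants` plus `record` (row index into `vt`), `region`
#'   and `mirna_id` (`NA` for region `"none"`).
#' @export
classify_variants <- function(vt, catalog) {
  v <- vt$variants
  vgr <- variant_granges(v)
  hgr <- catalog_granges(catalog$hairpins)
  hits <- GenomicRanges::findOverlaps(vgr, hgr)
  vi <- S4Vectors::queryHits(hits)
  hi <- S4Vectors::subjectHits(hits)

  rows <- data.frame(record = vi,
                     mirna_id = catalog$hairpins$mirna_id[hi],
                     region = rep("stem-loop", length(vi)),
                     stringsAsFactors = FALSE)
  # upgrade to mature, then seed, within the matched hairpin
  for (what in c("mature", "seed")) {
    feat <- if (what == "mature") catalog$arms else catalog$seeds
    if (!nrow(feat)) next
    fgr <- catalog_granges(feat)
    fh <- GenomicRanges::findOverlaps(vgr, fgr)
    key_f <- paste(S4Vectors::queryHits(fh), feat$mirna_id[S4Vectors::subjectHits(fh)])
    rows$region[paste(rows$record, rows$mirna_id) %in% key_f] <- what
  }
  outside <- setdiff(seq_len(nrow(v)), unique(vi))
  if (length(outside))
    rows <- rbind(rows, data.frame(record = outside, mirna_id = NA_character_,
                                   region = "none", stringsAsFactors = FALSE))
  rows <- rows[order(rows$record, rows$mirna_id), , drop = FALSE]
  out <- cbind(v[rows$record, , drop = FALSE], rows)
  rownames(out) <- NULL
  out
}

#' Flag novel variants
#'
#' Novel = absent from the known-sites resource (dbSNP-style membership).
#' Matching is allele-aware: a known record at the same position with a
#' different alternate allele does not make a variant known.
#'
#' @param vt a [variant_table()] (its `known` column was set allele-aware at
#'   VCF read time)
#' @return logical vector, `TRUE` where the variant is novel
#' @export
flag_novel <- function(vt) !vt$variants$known

#' Number of carrier individuals per variant
#' @param vt a [variant_table()]
#' @return integer vector: samples with dosage >= 1 (het or hom alt)
#' @export
n_carriers <- function(vt) {
  as.integer(rowSums(vt$geno >= 1L, na.rm = TRUE))
}

#' Remove undescribed singletons
#'
#' Novel variants carried by exactly one individual are removed as possible
#' somatic or sequencing artifacts; a single homozygous carrier still counts
#' as one individual. Known variants are never removed. Idempotent.
#'
#' @param vt a [variant_table()]
#' @return a filtered [variant_table()] with attribute `n_dropped`
#' @export
drop_singletons <- function(vt) {
  drop <- flag_novel(vt) & n_carriers(vt) == 1L
  out <- variant_table(vt$variants[!drop, , drop = FALSE],
                       vt$geno[!drop, , drop = FALSE], vt$panel)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Total bases per region class in a catalog
#'
#' Per hairpin, seed + mature + stem-loop base counts sum to the hairpin
#' length (the three classes partition it).
#'
#' @param catalog a [mirna_catalog()]
#' @return named numeric vector with elements `seed`, `mature`, `stem-loop`
#' @export
region_base_counts <- function(catalog) {
  hp_len <- sum(catalog$hairpins$end - catalog$hairpins$start + 1)
  arm_len <- sum(catalog$arms$end - catalog$arms$start + 1)
  seed_len <- sum(catalog$seeds$end - catalog$seeds$start + 1)
  c(seed = seed_len, mature = arm_len - seed_len,
    `stem-loop` = hp_len - arm_len)
}

#' Variant density (alleles per base) per region class
#'
#' @param annotated output of [classify_variants()]
#' @param catalog a [mirna_catalog()]
#' @param dedup if `TRUE` (default) a variant duplicated across overlapping
#'   hairpins counts once per region; if `FALSE` once per (variant, miRNA)
#' @return data.frame with `region`, `n_variants`, `bases`, `density`
#'   (density is `NA` for a region with zero bases)
#' @export
region_density <- function(annotated, catalog, dedup = TRUE) {
  ann <- annotated[annotated$region != "none", , drop = FALSE]
  if (dedup) ann <- ann[!duplicated(ann[, c("record", "region")]), , drop = FALSE]
  bases <- region_base_counts(catalog)
  n <- vapply(names(bases), function(r) sum(ann$region == r), numeric(1))
  data.frame(region = names(bases), n_variants = as.integer(n),
             bases = as.numeric(bases),
             density = ifelse(bases > 0, n / bases, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}
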