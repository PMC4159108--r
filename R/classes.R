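#' @importFrom methods is
#' @importFrom stats quantile rbinom rbeta runif setNames pt phyper p.adjust
#' @importFrom utils read.delim write.table
NULL

#' Construct a miRNA catalog
#'
#' A catalog holds the hairpin (pre-miRNA), mature-arm and seed intervals for a
#' set of miRNAs. All coordinates are 1-based closed intervals, the GFF3/VCF and
#' Bioconductor convention. Seed intervals are derived from the mature arms
#' (bases 2-8 from the 5' end of the arm) via [seed_interval()].
#'
#' @param hairpins data.frame with columns `mirna_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `confidence` (`"high"` or `"low"`, default
#'   `"low"`).
#' @param arms data.frame with columns `arm_id`, `mirna_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return An object of class `mirna_catalog`: a list with elements `hairpins`,
#'   `arms` and `seeds` (derived).
#' @export
mirna_catalog <- function(hairpins, arms) {
  req_h <- c("mirna_id", "chrom", "start", "end", "strand")
  req_a <- c("arm_id", "mirna_id", "chrom", "start", "end", "strand")
  if (!all(req_h %in% names(hairpins)))
    stop("hairpins must have columns: ", paste(req_h, collapse = ", "))
  if (!all(req_a %in% names(arms)))
    stop("arms must have columns: ", paste(req_a, collapse = ", "))
  if (anyDuplicated(hairpins$mirna_id))
    stop("duplicate mirna_id in hairpins")
  if (is.null(hairpins$confidence)) hairpins$confidence <- "low"
  hairpins <- as.data.frame(hairpins, stringsAsFactors = FALSE)
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)

  # every arm must lie inside its hairpin and be long enough to hold a seed
  m <- match(arms$mirna_id, hairpins$mirna_id)
  if (anyNA(m))
    stop("mature arm(s) with no parent hairpin: ",
         paste(arms$arm_id[is.na(m)], collapse = ", "))
  short <- (arms$end - arms$start + 1L) < 8L
  if (any(short))
    stop("mature arm(s) shorter than 8 nt: ",
         paste(arms$arm_id[short], collapse = ", "))
  outside <- arms$start < hairpins$start[m] | arms$end > hairpins$end[m] |
    arms$chrom != hairpins$chrom[m]
  if (any(outside))
    stop("mature arm(s) outside their hairpin: ",
         paste(arms$arm_id[outside], collapse = ", "))

  seeds <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    s <- seed_interval(c(arms$start[i], arms$end[i]), arms$strand[i])
    data.frame(arm_id = arms$arm_id[i], mirna_id = arms$mirna_id[i],
               chrom = arms$chrom[i], start = s[1], end = s[2],
               strand = arms$strand[i], stringsAsFactors = FALSE)
  }))
  if (is.null(seeds))
    seeds <- data.frame(arm_id = character(), mirna_id = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  structure(list(hairpins = hairpins, arms = arms, seeds = seeds),
            class = "mirna_catalog")
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat(sprintf("mirna_catalog: %d hairpins, %d mature arms, %d seeds\n",
              nrow(x$hairpins), nrow(x$arms), nrow(x$seeds)))
  invisible(x)
}

#' Construct a genome panel
#'
#' The sample manifest: one row per sequenced individual with its population,
#' continental region and hunter-gatherer / admixed flags. Per-population genome
#' counts are derived.
#'
#' @param df data.frame with columns `sample_id`, `population`, `region`,
#'   `hunter_gatherer`, `admixed`.
#' @return A `genome_panel` data.frame with an `n_genomes` attribute (named
#'   integer vector of individuals per population).
#' @export
genome_panel <- function(df) {
  req <- c("sample_id", "population", "region", "hunter_gatherer", "admixed")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("panel is missing required column(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in panel: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  # each population must map to exactly one region
  pr <- unique(df[, c("population", "region")])
  if (anyDuplicated(pr$population))
    stop("population(s) mapped to more than one region: ",
         paste(pr$population[duplicated(pr$population)], collapse = ", "))
  df$hunter_gatherer <- as.logical(df$hunter_gatherer)
  df$admixed <- as.logical(df$admixed)
  attr(df, "n_genomes") <- table_to_vector(table(df$population))
  class(df) <- c("genome_panel", "data.frame")
  df
}

table_to_vector <- function(tb) setNames(as.integer(tb), names(tb))

#' Per-population genome counts of a panel
#' @param panel a [genome_panel()]
#' @return named integer vector: number of sampled individuals per population
#' @export
n_genomes <- function(panel) attr(panel, "n_genomes")

#' Construct a variant table
#'
#' Biallelic variant records with an aligned genotype dosage matrix.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `variant_type` (`"SNP"`/`"indel"`), `known` (logical: present in the
#'   known-sites resource) and optionally `id`.
#' @param geno integer matrix (variants x samples) of alt-allele dosages
#'   0/1/2, `NA` for missing genotypes.
#' @param panel a [genome_panel()]; column order of `geno` must match
#'   `panel$sample_id`.
#' @return A `variant_table` object (list of `variants`, `geno`, `panel`).
#' @export
variant_table <- function(variants, geno, panel) {
  req <- c("chrom", "pos", "ref", "alt", "variant_type", "known")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants missing column(s): ",
                         paste(miss, collapse = ", "))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(variants))
    stop("geno rows (", nrow(geno), ") != variant records (", nrow(variants), ")")
  if (ncol(geno) != nrow(panel))
    stop("geno columns (", ncol(geno), ") != panel samples (", nrow(panel), ")")
  if (any(variants$alt == variants$ref))
    stop("alt == ref at record(s) ",
         paste(which(variants$alt == variants$ref), collapse = ", "))
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("genotype dosages must be 0, 1, 2 or NA")
  colnames(geno) <- panel$sample_id
  rownames(geno) <- NULL
  structure(list(variants = variants, geno = geno, panel = panel),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records x %d samples (%d SNP, %d indel)\n",
              nrow(x$variants), ncol(x$geno),
              sum(x$variants$variant_type == "SNP"),
              sum(x$variants$variant_type == "indel")))
  invisible(x)
}

#' Variant keys (chrom:pos:ref>alt) for a variant table or data.frame
#' @param x a `variant_table` or a data.frame with chrom/pos/ref/alt columns
#' @return character vector of keys
#' @export
variant_key <- function(x) {
  v <- if (is(x, "variant_table")) x$variants else x
  paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
}
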