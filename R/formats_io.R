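## I/O for every external format the pipeline touches. GFF3 goes through
## rtracklayer, VCF through VariantAnnotation; the plain TSV tables through
## base read.delim. All user-facing coordinates are 1-based inclusive.

#' Convert 1-based closed intervals to half-open 0-based (and back)
#'
#' Internally the package keeps the 1-based closed convention, but tools from
#' the BED/python world use half-open 0-based intervals; these helpers convert
#' between the two and are exact inverses of each other.
#'
#' @param start,end integer vectors (1-based closed for `coords_to_zero_based`,
#'   0-based half-open for `coords_to_one_based`)
#' @return data.frame with converted `start` and `end`
#' @export
coords_to_zero_based <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname coords_to_zero_based
#' @export
coords_to_one_based <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

gff_attr <- function(gr, field) {
  x <- S4Vectors::mcols(gr)[[field]]
  if (is.null(x)) return(rep(NA_character_, length(gr)))
  if (is(x, "List") || is.list(x))
    x <- vapply(x, function(v) if (length(v)) as.character(v[1]) else NA_character_,
                character(1))
  as.character(x)
}

#' Read a miRBase-style GFF3 annotation into a catalog
#'
#' Expects the miRBase dialect: `miRNA_primary_transcript` features for the
#' hairpins and `miRNA` features for the mature arms, linked to their hairpin
#' via the `Derives_from` attribute. Seed intervals (bases 2-8 from the 5' end
#' of each arm) are derived on load.
#'
#' @param path GFF3 file
#' @param confidence optional named character vector mapping mirna_id to
#'   `"high"`/`"low"`; unlisted miRNAs default to `"low"`
#' @return a [mirna_catalog()]
#' @export
read_mirna_gff <- function(path, confidence = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- gff_attr(gr, "ID")
  names_ <- gff_attr(gr, "Name")
  ids[is.na(ids)] <- names_[is.na(ids)]

  hp <- gr[type == "miRNA_primary_transcript"]
  arms <- gr[type == "miRNA"]
  if (length(hp) == 0) stop("no miRNA_primary_transcript features in ", path)

  hp_id <- gff_attr(hp, "ID")
  hairpins <- data.frame(
    mirna_id = ifelse(is.na(gff_attr(hp, "Name")), hp_id, gff_attr(hp, "Name")),
    chrom = as.character(GenomicRanges::seqnames(hp)),
    start = GenomicRanges::start(hp), end = GenomicRanges::end(hp),
    strand = as.character(GenomicRanges::strand(hp)),
    stringsAsFactors = FALSE)

  derives <- gff_attr(arms, "Derives_from")
  if (length(arms) && anyNA(derives))
    stop("mature miRNA feature(s) with no Derives_from parent link: ",
         paste(gff_attr(arms, "ID")[is.na(derives)], collapse = ", "))
  parent <- match(derives, hp_id)
  if (length(arms) && anyNA(parent))
    stop("mature miRNA feature(s) whose parent hairpin is absent: ",
         paste(gff_attr(arms, "ID")[is.na(parent)], collapse = ", "))
  armdf <- data.frame(
    arm_id = ifelse(is.na(gff_attr(arms, "Name")),
                    gff_attr(arms, "ID"), gff_attr(arms, "Name")),
    mirna_id = hairpins$mirna_id[parent],
    chrom = as.character(GenomicRanges::seqnames(arms)),
    start = GenomicRanges::start(arms), end = GenomicRanges::end(arms),
    strand = as.character(GenomicRanges::strand(arms)),
    stringsAsFactors = FALSE)

  if (!is.null(confidence)) {
    hairpins$confidence <- ifelse(hairpins$mirna_id %in% names(confidence),
                                  unname(confidence[hairpins$mirna_id]), "low")
  }
  mirna_catalog(hairpins, armdf)
}

#' Write a catalog back to miRBase-style GFF3
#' @param catalog a [mirna_catalog()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_mirna_gff <- function(catalog, path) {
  h <- catalog$hairpins
  a <- catalog$arms
  hp <- GenomicRanges::GRanges(h$chrom, IRanges::IRanges(h$start, h$end),
                               strand = h$strand)
  hp$type <- "miRNA_primary_transcript"
  hp$ID <- h$mirna_id
  hp$Name <- h$mirna_id
  hp$Derives_from <- NA_character_
  ar <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                               strand = a$strand)
  ar$type <- "miRNA"
  ar$ID <- a$arm_id
  ar$Name <- a$arm_id
  ar$Derives_from <- a$mirna_id
  gr <- c(hp, ar)
  gr$source <- "mirpopgen"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ID column straight off the VCF text; VariantAnnotation rewrites missing IDs
## into coordinate-style rownames, so we keep the raw field.
vcf_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(character())
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 3L)
}

split_gt_dosage <- function(gt, k) {
  # dosage of alt allele k within a GT string; any "." in the call -> NA;
  # other alt alleles count as reference (standard biallelic-split semantics)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == as.character(k))
  }, integer(1))
}

#' Read a VCF into a variant table
#'
#' Multi-allelic sites are split into one biallelic record per alternate
#' allele; for alt allele k, a sample's dosage counts its k alleles (other alt
#' alleles count as reference). `./.` and half-missing calls become `NA` —
#' no-call handling is explicit and documented. A record is "known" when its
#' ID column is non-missing or when (chrom, pos, ref, alt) appears in
#' `known_sites`. Records with non-ACGT alleles that are not simple indels
#' (symbolic alleles, `*`, `N`) are skipped with a warning.
#'
#' @param path VCF file (v4.x, plain text)
#' @param panel a [genome_panel()]; every panel sample must be a VCF sample
#' @param known_sites optional data.frame with columns chrom, pos, ref, alt of
#'   externally known sites (a dbSNP-style membership list)
#' @return a [variant_table()]
#' @export
read_vcf <- function(path, panel, known_sites = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf_samples <- colnames(vcf)
  missing_s <- setdiff(panel$sample_id, vcf_samples)
  if (length(missing_s))
    stop("panel sample(s) absent from VCF: ", paste(missing_s, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  gt <- gt[, panel$sample_id, drop = FALSE]
  ids <- vcf_id_column(path)

  known_key <- character()
  if (!is.null(known_sites))
    known_key <- paste0(known_sites$chrom, ":", known_sites$pos, ":",
                        known_sites$ref, ">", known_sites$alt)

  out_var <- list(); out_gen <- list(); skipped <- character()
  for (i in seq_along(rr)) {
    alts <- as.character(alt_list[[i]])
    for (k in seq_along(alts)) {
      alt <- alts[k]
      ok_snp <- nchar(ref[i]) == 1 && nchar(alt) == 1 &&
        grepl("^[ACGT]$", ref[i]) && grepl("^[ACGT]$", alt)
      ok_indel <- nchar(ref[i]) != nchar(alt) &&
        grepl("^[ACGT]+$", ref[i]) && grepl("^[ACGT]+$", alt)
      if (!ok_snp && !ok_indel) {
        skipped <- c(skipped, paste0(chrom[i], ":", pos[i], " ", ref[i], ">", alt))
        next
      }
      key <- paste0(chrom[i], ":", pos[i], ":", ref[i], ">", alt)
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt,
        variant_type = if (ok_snp) "SNP" else "indel",
        id = if (ids[i] == ".") NA_character_ else ids[i],
        known = ids[i] != "." || key %in% known_key,
        stringsAsFactors = FALSE)
      out_gen[[length(out_gen) + 1L]] <- split_gt_dosage(gt[i, ], k)
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " record(s) with unsupported alleles: ",
            paste(utils::head(skipped, 5), collapse = "; "))
  if (!length(out_var))
    return(variant_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), variant_type = character(),
                 id = character(), known = logical()),
      matrix(integer(), 0, nrow(panel)), panel))
  variant_table(do.call(rbind, out_var), do.call(rbind, out_gen), panel)
}

read_headered_tsv <- function(path, required, what) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read the sample manifest
#'
#' Headered TSV with columns `sample_id`, `population`, `region`,
#' `hunter_gatherer`, `admixed`.
#'
#' @param path TSV file
#' @return a [genome_panel()]
#' @export
read_panel <- function(path) {
  genome_panel(read_headered_tsv(
    path, c("sample_id", "population", "region", "hunter_gatherer", "admixed"),
    "panel"))
}

#' Read the miRNA-target evidence table
#'
#' Headered TSV with columns `mirna_id`, `gene_id`, `dataset_id`, `r` (the
#' miRNA/mRNA expression correlation in a dataset). Rows with `r` outside
#' `[-1, 1]` are rejected with a warning; duplicated (mirna, gene, dataset)
#' triples are collapsed to their first occurrence with a warning.
#'
#' @param path TSV file
#' @return data.frame (the TargetEvidenceTable)
#' @export
read_evidence <- function(path) {
  df <- read_headered_tsv(path, c("mirna_id", "gene_id", "dataset_id", "r"),
                          "evidence")
  bad <- !is.finite(df$r) | df$r < -1 | df$r > 1
  if (any(bad)) {
    warning("rejected ", sum(bad), " evidence row(s) with r outside [-1, 1]")
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$mirna_id, df$gene_id, df$dataset_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)),
            " duplicate (mirna, gene, dataset) evidence row(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read the gene -> GO biological-process annotation table
#'
#' Headered TSV with columns `gene_id`, `process_id`. The background gene
#' universe defaults to all annotated genes; supply `background` to widen it.
#'
#' @param path TSV file
#' @param background optional character vector of background genes (must
#'   contain all annotated genes)
#' @return list with `annotations` (data.frame) and `background` (character)
#' @export
read_go <- function(path, background = NULL) {
  df <- read_headered_tsv(path, c("gene_id", "process_id"), "GO annotation")
  df <- unique(df[, c("gene_id", "process_id")])
  if (is.null(background)) background <- unique(df$gene_id)
  if (!all(df$gene_id %in% background))
    stop("background gene universe does not contain all annotated genes")
  list(annotations = df, background = background)
}

#' Read the miRNA -> disease association table
#'
#' Headered TSV with columns `mirna_id`, `disease_name`, `direction`
#' (up/down/both/unknown). Duplicate (mirna, disease) pairs collapse with a
#' warning. An empty table (header only) is valid.
#'
#' @param path TSV file
#' @return data.frame (the DiseaseAssociationTable)
#' @export
read_disease <- function(path) {
  df <- read_headered_tsv(path, c("mirna_id", "disease_name", "direction"),
                          "disease")
  key <- paste(df$mirna_id, df$disease_name, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)),
            " duplicate (mirna, disease) row(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a result table as TSV with a provenance comment header
#'
#' @param df data.frame to write
#' @param path output file
#' @param extra named character vector of extra `key=value` comment entries
#'   (e.g. thresholds, config hash)
#' @return `path`, invisibly
#' @export
write_result_tsv <- function(df, path, extra = NULL) {
  hdr <- sprintf("# mirpopgen %s",
                 as.character(utils::packageVersion("mirpopgen")))
  if (!is.null(extra))
    hdr <- c(hdr, paste0("# ", names(extra), "=", unname(extra)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Hash an R object (for config provenance in output headers)
#' @param x any serialisable object
#' @return md5 hex string
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
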