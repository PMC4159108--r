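# Fixtures are built in code; no binary data anywhere.

tiny_catalog <- function() {
  # two hairpins on opposite strands, chr1; arms at both ends
  hairpins <- data.frame(
    mirna_id = c("mir-A", "mir-B"), chrom = "chr1",
    start = c(1000L, 2000L), end = c(1084L, 2090L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  arms <- data.frame(
    arm_id = c("mir-A-5p", "mir-A-3p", "mir-B-5p", "mir-B-3p"),
    mirna_id = c("mir-A", "mir-A", "mir-B", "mir-B"),
    chrom = "chr1",
    start = c(1000L, 1063L, 2000L, 2069L),
    end = c(1021L, 1084L, 2021L, 2090L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  mirna_catalog(hairpins, arms)
}

tiny_panel <- function(pops = c(A = 3L, B = 3L),
                       regions = NULL, admixed = character()) {
  if (is.null(regions))
    regions <- setNames(rep(c("Africa", "Europe"), length.out = length(pops)),
                        names(pops))
  df <- do.call(rbind, lapply(names(pops), function(p) {
    data.frame(sample_id = sprintf("%s_%02d", p, seq_len(pops[[p]])),
               population = p, region = regions[[p]],
               hunter_gatherer = FALSE, admixed = p %in% admixed,
               stringsAsFactors = FALSE)
  }))
  genome_panel(df)
}

# hand-rolled VCF writer for malformed/edge-case inputs the package writer
# would refuse to produce
write_raw_vcf <- function(path, samples, records) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vt_from_geno <- function(geno, panel, known = rep(TRUE, nrow(geno)),
                         type = rep("SNP", nrow(geno)),
                         chrom = "chr1", pos = seq_len(nrow(geno)) * 100L,
                         ref = rep("A", nrow(geno)),
                         alt = rep("G", nrow(geno))) {
  variant_table(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               variant_type = type, id = ifelse(known, "rs1", NA_character_),
               known = known, stringsAsFactors = FALSE),
    geno, panel)
}

# brute-force oracles ---------------------------------------------------------

# per-base region labelling: the label of a multi-base variant within one
# hairpin is the highest-precedence label among its overlapped bases
bf_classify <- function(chrom, pos, ref, catalog) {
  span <- pos:(pos + nchar(ref) - 1L)
  out <- list()
  for (i in seq_len(nrow(catalog$hairpins))) {
    h <- catalog$hairpins[i, ]
    if (h$chrom != chrom) next
    hit <- span[span >= h$start & span <= h$end]
    if (!length(hit)) next
    labels <- vapply(hit, function(b) {
      sd <- catalog$seeds[catalog$seeds$mirna_id == h$mirna_id, ]
      if (any(b >= sd$start & b <= sd$end)) return("seed")
      ar <- catalog$arms[catalog$arms$mirna_id == h$mirna_id, ]
      if (any(b >= ar$start & b <= ar$end)) return("mature")
      "stem-loop"
    }, character(1))
    best <- c("seed", "mature", "stem-loop")[
      min(match(labels, c("seed", "mature", "stem-loop")))]
    out[[h$mirna_id]] <- best
  }
  out
}

# seed by explicit 5'->3' base enumeration along the mature arm
bf_seed <- function(start, end, strand) {
  walk <- if (strand == "+") start:end else end:start
  range(walk[2:8])
}

# Weir-Cockerham theta by literal ANOVA mean squares on 0/1 chromosome data
bf_fst_anova <- function(c1, n1, c2, n2) {
  x <- c(rep(1, c1), rep(0, n1 - c1), rep(1, c2), rep(0, n2 - c2))
  g <- rep(1:2, c(n1, n2))
  p_i <- tapply(x, g, mean)
  gm <- mean(x)
  ssa <- sum(c(n1, n2) * (p_i - gm)^2)
  ssw <- sum((x - p_i[g])^2)
  msa <- ssa / (2 - 1)
  msw <- ssw / (n1 + n2 - 2)
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (2 - 1)
  denom <- msa + (nc - 1) * msw
  if (abs(denom) < 1e-300) return(NA_real_)
  (msa - msw) / denom
}
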