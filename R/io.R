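# File formats: TSV haplotype / genotype tables, minimal two-site VCF
# input (via VariantAnnotation), run configuration (JSON or YAML), and the
# fixture generator used by tests and docs.
#
# TSV dialect: tab-separated, header required, '.' treated as missing.

#' Read a phased haplotype table
#'
#' Expects a TSV with header columns `individual_id`, `line`, `allele_M`,
#' `allele_N`, exactly two rows per individual (one for the line-A
#' haplotype, one for line-B), alleles coded 0/1.
#'
#' @param path Path to the TSV file.
#' @return A [pair_counts()] table with n = number of individuals.
#' @export
read_haplotype_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", na.strings = ".")
  required <- c("individual_id", "line", "allele_M", "allele_N")
  if (!all(required %in% names(tab))) {
    stop(sprintf("haplotype table %s: missing column(s) %s", path,
                 paste(setdiff(required, names(tab)), collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("allele_M", "allele_N")) {
    bad <- which(!(tab[[col]] %in% c("0", "1")))
    if (length(bad)) {
      stop(sprintf("haplotype table %s: non-binary %s at data row %d",
                   path, col, bad[1]), call. = FALSE)
    }
  }
  bad <- which(!(tab$line %in% c("A", "B")))
  if (length(bad)) {
    stop(sprintf("haplotype table %s: invalid line symbol at data row %d",
                 path, bad[1]), call. = FALSE)
  }
  key <- paste(tab$individual_id, tab$line)
  if (anyDuplicated(key)) {
    stop(sprintf("haplotype table %s: duplicate (individual, line) at data row %d",
                 path, anyDuplicated(key)), call. = FALSE)
  }
  ids <- unique(tab$individual_id)
  hap_idx <- 2L * as.integer(tab$allele_M) + as.integer(tab$allele_N) + 1L
  counts <- matrix(0, 4, 4)
  rowA <- match(paste(ids, "A"), key)
  rowB <- match(paste(ids, "B"), key)
  if (anyNA(rowA) || anyNA(rowB)) {
    missing_id <- ids[which(is.na(rowA) | is.na(rowB))[1]]
    stop(sprintf("haplotype table %s: individual '%s' lacks a haplotype for one line",
                 path, missing_id), call. = FALSE)
  }
  for (k in seq_along(ids)) {
    counts[hap_idx[rowA[k]], hap_idx[rowB[k]]] <-
      counts[hap_idx[rowA[k]], hap_idx[rowB[k]]] + 1
  }
  pair_counts(counts)
}

#' Read an unphased genotype-dosage table
#'
#' Expects a TSV with header columns `individual_id`, `dosage_M`,
#' `dosage_N`, one row per individual, dosages in 0/1/2.
#'
#' @param path Path to the TSV file.
#' @return A [dosage_sample()] table.
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", na.strings = ".")
  required <- c("individual_id", "dosage_M", "dosage_N")
  if (!all(required %in% names(tab))) {
    stop(sprintf("genotype table %s: missing column(s) %s", path,
                 paste(setdiff(required, names(tab)), collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("dosage_M", "dosage_N")) {
    bad <- which(!(tab[[col]] %in% c("0", "1", "2")))
    if (length(bad)) {
      stop(sprintf("genotype table %s: invalid %s at data row %d", path,
                   col, bad[1]), call. = FALSE)
    }
  }
  if (anyDuplicated(tab$individual_id)) {
    stop(sprintf("genotype table %s: duplicate individual_id at data row %d",
                 path, anyDuplicated(tab$individual_id)), call. = FALSE)
  }
  counts <- matrix(0, 3, 3)
  for (k in seq_len(nrow(tab))) {
    i <- as.integer(tab$dosage_M[k]) + 1L
    j <- as.integer(tab$dosage_N[k]) + 1L
    counts[i, j] <- counts[i, j] + 1
  }
  dosage_sample(counts)
}

#' Read two biallelic sites from a VCF
#'
#' Extracts the GT field at the two requested sites. Fully phased
#' genotypes (`|` separator) together with a line map yield phase-resolved
#' [pair_counts()]; unphased (`/`) or mixed phasing yields a
#' [dosage_sample()] (with a warning when phasing is mixed). Dosage counts
#' the ALT allele.
#'
#' @param path Path to a VCF (v4.x, plain or bgzipped).
#' @param locus_m,locus_n Site coordinates as `"chrom:pos"` (1-based).
#' @param line_map Optional path to a TSV with columns `individual_id`,
#'   `hap1_line`, `hap2_line` assigning each phased haplotype (first /
#'   second GT field) to parental line A or B. Required for phased input:
#'   parental origin cannot be inferred from the VCF alone.
#' @return A [pair_counts()] (phased + line map) or [dosage_sample()].
#' @export
read_vcf_pair <- function(path, locus_m, locus_n, line_map = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("package 'VariantAnnotation' is required for VCF input",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop(sprintf("VCF %s: no GT field", path), call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  site_key <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                     GenomicRanges::start(rr))
  pick <- function(locus) {
    hit <- which(site_key == locus)
    if (length(hit) == 0) {
      stop(sprintf("VCF %s: site %s not found", path, locus), call. = FALSE)
    }
    if (length(hit) > 1) {
      stop(sprintf("VCF %s: site %s is duplicated", path, locus),
           call. = FALSE)
    }
    alts <- rr$ALT[[hit]]
    if (length(alts) != 1) {
      stop(sprintf("VCF %s: site %s is not biallelic", path, locus),
           call. = FALSE)
    }
    gt[hit, ]
  }
  gtM <- pick(locus_m)
  gtN <- pick(locus_n)
  if (any(grepl("\\.", c(gtM, gtN)))) {
    stop(sprintf("VCF %s: missing genotypes are not supported", path),
         call. = FALSE)
  }
  phased <- all(grepl("\\|", c(gtM, gtN)))
  unphased <- all(grepl("/", c(gtM, gtN)))
  split_gt <- function(g) {
    parts <- strsplit(g, "[|/]")
    al <- suppressWarnings(vapply(parts, function(p) as.integer(p[1:2]),
                                  integer(2)))
    if (anyNA(al) || any(al > 1)) {
      stop(sprintf("VCF %s: non-biallelic or malformed GT", path),
           call. = FALSE)
    }
    al  # 2 x n_samples: first / second haplotype allele
  }
  alM <- split_gt(gtM)
  alN <- split_gt(gtN)
  if (phased && !is.null(line_map)) {
    lm <- utils::read.delim(line_map, colClasses = "character")
    required <- c("individual_id", "hap1_line", "hap2_line")
    if (!all(required %in% names(lm))) {
      stop(sprintf("line map %s: missing column(s) %s", line_map,
                   paste(setdiff(required, names(lm)), collapse = ", ")),
           call. = FALSE)
    }
    samples <- colnames(gt)
    idx <- match(samples, lm$individual_id)
    if (anyNA(idx)) {
      stop(sprintf("line map %s: sample '%s' not mapped", line_map,
                   samples[which(is.na(idx))[1]]), call. = FALSE)
    }
    counts <- matrix(0, 4, 4)
    for (k in seq_along(samples)) {
      lines2 <- c(lm$hap1_line[idx[k]], lm$hap2_line[idx[k]])
      if (!setequal(lines2, c("A", "B"))) {
        stop(sprintf("line map %s: sample '%s' must have one A and one B haplotype",
                     line_map, samples[k]), call. = FALSE)
      }
      whichA <- which(lines2 == "A")
      whichB <- which(lines2 == "B")
      hapA <- 2L * alM[whichA, k] + alN[whichA, k] + 1L
      hapB <- 2L * alM[whichB, k] + alN[whichB, k] + 1L
      counts[hapA, hapB] <- counts[hapA, hapB] + 1
    }
    return(pair_counts(counts))
  }
  if (phased && is.null(line_map)) {
    stop("phased VCF input requires a line map: parental origin of each haplotype cannot be inferred",
         call. = FALSE)
  }
  if (!unphased) {
    warning("mixed phased/unphased genotypes: falling back to dosages",
            call. = FALSE)
  }
  counts <- matrix(0, 3, 3)
  dM <- colSums(alM)
  dN <- colSums(alN)
  for (k in seq_along(dM)) {
    counts[dM[k] + 1L, dN[k] + 1L] <- counts[dM[k] + 1L, dN[k] + 1L] + 1
  }
  dosage_sample(counts)
}

#' Write a synthetic crossbred dataset for one scenario
#'
#' Seeds the RNG from the scenario seed, samples one replicate, and writes
#' plain-text files under `dir`: `haplotypes.tsv` (phased, two rows per
#' individual), `genotypes.tsv` (unphased dosages), a phased two-site VCF
#' `sites.vcf` with matching `line_map.tsv`, and `truth.json` holding the
#' scenario parameters and the true crossbred LD. Re-running with the same
#' scenario produces byte-identical files.
#'
#' @param scn A [cross_scenario()].
#' @param dir Output directory (created if needed).
#' @param format `"both"` (default), `"tsv"`, or `"vcf"`.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(scn, dir, format = c("both", "tsv", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scn$seed)
  pc <- sample_crossbred(scn)
  true <- crossbred_true_ld(scn$hA, scn$hB)
  # expand counts to per-individual haplotype pairs in fixed cell order
  cells <- which(unclass(pc) > 0, arr.ind = TRUE)
  hapA <- rep(cells[, 1], unclass(pc)[cells])
  hapB <- rep(cells[, 2], unclass(pc)[cells])
  n <- length(hapA)
  ids <- sprintf("ind_%04d", seq_len(n))
  files <- character(0)
  if (format %in% c("both", "tsv")) {
    hap_tab <- data.frame(
      individual_id = rep(ids, each = 2),
      line = rep(c("A", "B"), n),
      allele_M = as.vector(rbind(.ALLELE_M[hapA], .ALLELE_M[hapB])),
      allele_N = as.vector(rbind(.ALLELE_N[hapA], .ALLELE_N[hapB])))
    f <- file.path(dir, "haplotypes.tsv")
    utils::write.table(hap_tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["haplotypes"] <- f
    gen_tab <- data.frame(
      individual_id = ids,
      dosage_M = .ALLELE_M[hapA] + .ALLELE_M[hapB],
      dosage_N = .ALLELE_N[hapA] + .ALLELE_N[hapB])
    f <- file.path(dir, "genotypes.tsv")
    utils::write.table(gen_tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["genotypes"] <- f
  }
  if (format %in% c("both", "vcf")) {
    f <- file.path(dir, "sites.vcf")
    gtM <- paste0(.ALLELE_M[hapA], "|", .ALLELE_M[hapB])
    gtN <- paste0(.ALLELE_N[hapA], "|", .ALLELE_N[hapB])
    header <- c(
      "##fileformat=VCFv4.2",
      "##contig=<ID=1>",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", ids), collapse = "\t"))
    rows <- c(
      paste(c("1", "1000", "locus_M", "A", "C", ".", "PASS", ".", "GT",
              gtM), collapse = "\t"),
      paste(c("1", "2000", "locus_N", "A", "C", ".", "PASS", ".", "GT",
              gtN), collapse = "\t"))
    writeLines(c(header, rows), f)
    files["vcf"] <- f
    f <- file.path(dir, "line_map.tsv")
    utils::write.table(
      data.frame(individual_id = ids, hap1_line = "A", hap2_line = "B"),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["line_map"] <- f
  }
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(pM_A = scn$pM_A, pN_A = scn$pN_A, pM_B = scn$pM_B, pN_B = scn$pN_B,
         r2_A = scn$r2_A, r2_B = scn$r2_B, phase_A = scn$phase_A,
         phase_B = scn$phase_B, n = n, seed = scn$seed,
         true_r2 = true$r2, true_D = true$D, true_Dprime = true$Dprime),
    f, auto_unbox = TRUE, digits = NA)
  files["truth"] <- f
  invisible(files)
}

.CONFIG_KEYS <- c("freq_levels", "r2_levels", "sample_sizes", "n_reps",
                  "seed", "phase", "keep_replicates")

#' Read a simulation run configuration
#'
#' JSON (default) or YAML (by `.yml`/`.yaml` extension; requires the
#' `yaml` package). Recognised keys: `freq_levels`, `r2_levels`,
#' `sample_sizes`, `n_reps`, `seed`, `phase`, `keep_replicates`. Unknown
#' keys are rejected; values are validated by building the scenario grid.
#'
#' @param path Path to the config file.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("package 'yaml' is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("config %s: unknown key(s) %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(freq_levels = c(0.05, 0.15, 0.25, 0.35, 0.45),
                   r2_levels = c(0.2, 0.4, 0.6, 0.8),
                   sample_sizes = c(900, 1800, 2700),
                   n_reps = 1000, seed = 1, phase = 1,
                   keep_replicates = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  # fail fast on infeasible combinations
  invisible(build_scenario_grid(cfg$freq_levels, cfg$r2_levels,
                                cfg$sample_sizes, n_reps = 1,
                                seed = cfg$seed, phase = cfg$phase))
  structure(cfg, class = "run_config")
}

#' Serialise a run configuration to JSON
#'
#' @param cfg A `"run_config"` list.
#' @param path Output path.
#' @return Invisibly, `path`. `read_run_config(path)` round-trips to an
#'   identical configuration.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
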