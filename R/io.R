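#' Write a cohort to delimited files
#'
#' Writes (a) a phenotype table (`<prefix>_phenotypes.tsv`: id, cohort,
#' stratum, sex, gestational_days, one column per exclusion flag) and (b) a
#' dosage matrix, either tab-delimited (`<prefix>_dosages.tsv`, id x SNP) or
#' a minimal VCF with a per-genotype `DS` (dosage) field where the effect
#' allele is ALT (`<prefix>_dosages.vcf`).
#'
#' @param cohort A `duo_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default the cohort id).
#' @param dosage_format `"tsv"` or `"vcf"`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = cohort$cohort_id[1],
                         dosage_format = c("tsv", "vcf")) {
  dosage_format <- match.arg(dosage_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_individuals(cohort)
  ids <- sprintf("%s_%06d", prefix, seq_len(n))
  pheno <- data.frame(
    id = ids, cohort = cohort$cohort_id, stratum = cohort$stratum,
    sex = cohort$sex, gestational_days = cohort$gestational_days,
    cohort$exclusion_flags, stringsAsFactors = FALSE
  )
  pheno_path <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  utils::write.table(pheno, pheno_path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (dosage_format == "tsv") {
    dos <- data.frame(id = ids, cohort$child_dosage, check.names = FALSE)
    dosage_path <- file.path(dir, paste0(prefix, "_dosages.tsv"))
    utils::write.table(dos, dosage_path,
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dosage_path <- file.path(dir, paste0(prefix, "_dosages.vcf"))
    write_dosage_vcf(cohort$child_dosage, cohort$snp_meta, ids, dosage_path)
  }
  invisible(c(phenotypes = pheno_path, dosages = dosage_path))
}

#' Write a dosage matrix as a minimal VCF with a DS field
#'
#' The effect allele is written as ALT so that standard `DS` semantics
#' (expected ALT allele count in \[0, 2\]) match the package's dosage
#' convention. Positions are synthetic 1-based coordinates.
#'
#' @param dosage Individuals x SNPs matrix.
#' @param snp_meta Data frame with `snp_id`, `effect_allele`, `other_allele`.
#' @param ids Sample identifiers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(dosage, snp_meta, ids, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dosage)), function(j) {
    ds <- ifelse(is.na(dosage[, j]), ".", formatC(dosage[, j], format = "g"))
    paste(c("1", as.character(j), snp_meta$snp_id[j],
      snp_meta$other_allele[j], snp_meta$effect_allele[j],
      ".", "PASS", ".", "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype table
#' @param path Tab-delimited file written by [write_cohort()].
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read an allelic dosage matrix
#'
#' Reads either the package's tab-delimited id-by-SNP layout or a VCF whose
#' genotypes carry a `DS` (dosage) field; for VCF input the effect allele is
#' ALT. Missing entries (`"."` or empty) become `NA`. Dosages outside
#' \[0, 2\] raise an error naming the offending row and column.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf_ds"`.
#' @return List with `dosage` (individuals x SNPs numeric matrix, rownames =
#'   sample ids) and `snp_meta` (snp_id, effect_allele, other_allele).
#' @export
read_dosages <- function(path, format = c("tsv", "vcf_ds")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
      stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", "."))
    mat <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- tab[[1]]
    meta <- data.frame(
      snp_id = colnames(mat), effect_allele = NA_character_,
      other_allele = NA_character_, stringsAsFactors = FALSE
    )
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS")
    if (is.null(ds) || all(is.na(ds))) {
      stop("VCF has no per-genotype DS (dosage) field", call. = FALSE)
    }
    mat <- matrix(suppressWarnings(as.numeric(ds)), nrow(ds), ncol(ds))
    mat <- t(mat) # individuals x SNPs
    fix <- vcfR::getFIX(v)
    fix <- if (is.null(dim(fix))) t(fix) else fix
    colnames(mat) <- fix[, "ID"]
    rownames(mat) <- colnames(ds)
    meta <- data.frame(
      snp_id = fix[, "ID"], effect_allele = fix[, "ALT"],
      other_allele = fix[, "REF"], stringsAsFactors = FALSE
    )
  }
  bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "dosage outside [0, 2] at row %s, column %s",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), call. = FALSE)
  }
  list(dosage = mat, snp_meta = meta)
}

#' Write per-SNP association summary statistics
#'
#' Tab-delimited with columns SNP, EA, NEA, EAF, EFFECT, SE, P, N, N_CASES,
#' N_CONTROLS, INFO, TRAIT, COHORT, STRATUM. A leading header comment
#' records the effect scale (`beta` for quantitative traits, `log_or` for
#' binary traits).
#'
#' @param estimates List of `assoc_estimate` objects or an equivalent data
#'   frame.
#' @param path Output path.
#' @param scale `"beta"` or `"log_or"`.
#' @param snp_meta Optional data frame supplying EA/NEA/INFO by `snp_id`.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(estimates, path, scale = c("beta", "log_or"),
                                snp_meta = NULL) {
  scale <- match.arg(scale)
  df <- if (is.data.frame(estimates)) estimates else summary_stats_frame(estimates)
  if (!is.null(snp_meta)) {
    m <- match(df$SNP, snp_meta$snp_id)
    df$EA <- snp_meta$effect_allele[m]
    df$NEA <- snp_meta$other_allele[m]
    if ("info" %in% names(snp_meta)) df$INFO <- snp_meta$info[m]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# effect_scale=%s", scale), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten association estimates into a summary-statistics data frame
#' @param estimates List of `assoc_estimate` objects.
#' @return Data frame with the standard summary-statistics columns.
#' @export
summary_stats_frame <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(
      SNP = e$snp_id, EA = NA_character_, NEA = NA_character_,
      EAF = e$eaf, EFFECT = e$effect, SE = e$se, P = e$p, N = e$n,
      N_CASES = e$n_cases, N_CONTROLS = e$n_controls, INFO = e$quality,
      TRAIT = e$trait, COHORT = e$cohort_id, STRATUM = e$stratum,
      stringsAsFactors = FALSE
    )
  }))
}

#' Read per-SNP summary statistics
#'
#' Requires a header with at least SNP, EA, NEA, EFFECT, and SE (or enough
#' to recover SE: CI_LOW/CI_HIGH or P). Alleles are upper-cased; the effect
#' scale is inferred from the `# effect_scale=` header comment when present.
#' Malformed rows (non-positive SE, missing effect) are collected into an
#' `errors` report rather than silently dropped.
#'
#' @param path Input file.
#' @return List with `records` (typed data frame with attribute `"scale"`)
#'   and `errors` (data frame of rejected rows with a `reason` column).
#' @export
read_summary_stats <- function(path) {
  first <- readLines(path, n = 1)
  scale <- if (grepl("^#\\s*effect_scale=", first)) {
    sub("^#\\s*effect_scale=", "", first)
  } else {
    "beta"
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, comment.char = "#")
  required <- c("SNP", "EA", "NEA", "EFFECT")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE)
  }
  if (!"SE" %in% names(tab)) {
    if (all(c("CI_LOW", "CI_HIGH") %in% names(tab))) {
      tab$SE <- ci_to_se(tab$CI_LOW, tab$CI_HIGH)
    } else if ("P" %in% names(tab)) {
      tab$SE <- p_to_se(tab$EFFECT, tab$P)
    } else {
      stop("missing required column(s): SE (and no CI or P to recover it)",
        call. = FALSE)
    }
  }
  tab$EA <- toupper(tab$EA)
  tab$NEA <- toupper(tab$NEA)
  bad <- is.na(tab$EFFECT) | is.na(tab$SE) | tab$SE <= 0
  errors <- tab[bad, , drop = FALSE]
  if (nrow(errors) > 0) {
    errors$reason <- ifelse(is.na(tab$EFFECT[bad]), "missing effect",
      ifelse(is.na(tab$SE[bad]), "missing SE", "non-positive SE"))
  } else {
    errors$reason <- character(0)
  }
  records <- tab[!bad, , drop = FALSE]
  attr(records, "scale") <- scale
  list(records = records, errors = errors)
}

.STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize summary statistics to a reference allele orientation
#'
#' Aligns records to a reference by SNP id: where the effect/other alleles
#' are swapped relative to the reference, the effect sign is flipped and the
#' effect-allele frequency complemented. Records whose alleles do not match
#' the reference in either orientation, or which are strand-ambiguous (A/T,
#' C/G) and mismatched, are dropped with a warning.
#'
#' @param records Summary-statistics data frame (SNP, EA, NEA, EFFECT, and
#'   optionally EAF).
#' @param reference Data frame with SNP, EA, NEA giving the target
#'   orientation.
#' @return The harmonized data frame with a logical `flipped` column.
#' @export
harmonize_alleles <- function(records, reference) {
  m <- match(records$SNP, reference$SNP)
  if (anyNA(m)) {
    warning(sprintf("%d record(s) absent from the reference were dropped", sum(is.na(m))),
      call. = FALSE)
    records <- records[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  ref_ea <- toupper(reference$EA[m])
  ref_nea <- toupper(reference$NEA[m])
  same <- records$EA == ref_ea & records$NEA == ref_nea
  swapped <- records$EA == ref_nea & records$NEA == ref_ea
  ambiguous <- paste(records$EA, records$NEA, sep = "/") %in% .STRAND_AMBIGUOUS
  drop <- !(same | swapped) | (ambiguous & !same)
  if (any(drop)) {
    warning(sprintf(
      "%d record(s) dropped during harmonization (allele mismatch or strand-ambiguous)",
      sum(drop)
    ), call. = FALSE)
  }
  out <- records[!drop, , drop = FALSE]
  flip <- swapped[!drop]
  out$EFFECT[flip] <- -out$EFFECT[flip]
  if ("EAF" %in% names(out)) out$EAF[flip] <- 1 - out$EAF[flip]
  tmp <- out$EA[flip]
  out$EA[flip] <- out$NEA[flip]
  out$NEA[flip] <- tmp
  out$flipped <- flip
  out
}

#' Read a published-rows CSV for literature meta-analysis
#'
#' Expects columns label, effect, ci_low, ci_high, p, scale (and optionally
#' n); returns a list of [study_row()] objects ready for [ivw_meta()].
#'
#' @param path CSV path.
#' @return List of `study_row` objects.
#' @export
read_published_rows <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "effect", "scale")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE)
  }
  get <- function(col, i) if (col %in% names(tab)) tab[[col]][i] else NA
  lapply(seq_len(nrow(tab)), function(i) {
    study_row(
      label = tab$label[i], effect = tab$effect[i],
      ci_low = get("ci_low", i), ci_high = get("ci_high", i),
      p = get("p", i), n = get("n", i), scale = tab$scale[i]
    )
  })
}
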