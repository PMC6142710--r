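# Readers/writers for the plain-text formats the pipeline touches:
# PLINK .raw-style dosage tables, VCF (GT only), pedigree CSV,
# phenotype/kernel TSV, YAML configuration, and run manifests.

#' Write genotypes
#'
#' `plink_raw` writes the whitespace table `FID IID PAT MAT SEX
#' PHENOTYPE` followed by one dosage column per locus. `tsv` writes a
#' plain id + dosage table. `vcf` writes an unphased GT-only VCF;
#' base-pair positions are fabricated as `round(cM * 1e4)` (the map is
#' simulation-native, in centimorgans).
#'
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @param format `"plink_raw"`, `"tsv"` or `"vcf"`.
#' @param pedigree optional `pedigree` supplying PAT/MAT/SEX columns.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path,
                            format = c("plink_raw", "tsv", "vcf"),
                            pedigree = NULL) {
  format <- match.arg(format)
  dos <- geno$dosage
  ids <- rownames(dos)
  if (format == "tsv") {
    df <- data.frame(id = ids, dos, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "plink_raw") {
    pat <- mat <- rep("0", length(ids))
    sex <- rep(0L, length(ids))
    if (!is.null(pedigree)) {
      i <- match(ids, pedigree$id)
      pat <- ifelse(is.na(i), "0", as.character(pedigree$sire[i]))
      mat <- ifelse(is.na(i), "0", as.character(pedigree$dam[i]))
      sex <- ifelse(is.na(i), 0L, ifelse(pedigree$sex[i] == "M", 1L, 2L))
    }
    df <- data.frame(FID = ids, IID = ids, PAT = pat, MAT = mat, SEX = sex,
                     PHENOTYPE = -9, dos, check.names = FALSE)
    write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  } else {
    loci <- geno$map$loci
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=genoconnect",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
               con)
    gt <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(dos))) {
      row <- c(loci$chrom[j], round(loci$pos_cM[j] * 1e4), loci$id[j],
               "A", "B", ".", "PASS", ".", "GT", gt[dos[, j] + 1L])
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes
#'
#' Accepts the three dialects written by [write_genotypes()]. Missing
#' genotypes are imputed to twice the allele frequency rounded to the
#' nearest dosage, with a message; non-biallelic VCF records are
#' skipped with a count. VCF parsing uses the vcfR package.
#'
#' @param path input file.
#' @param format `"plink_raw"`, `"tsv"` or `"vcf"`.
#' @param map optional `genome_map` to attach; otherwise a single
#'   pseudo-chromosome map with unit spacing is fabricated.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("plink_raw", "tsv", "vcf"),
                           map = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    ids <- as.character(df[[1L]])
    dos <- as.matrix(df[, -1L, drop = FALSE])
  } else if (format == "plink_raw") {
    df <- read.table(path, header = TRUE, check.names = FALSE)
    ids <- as.character(df$IID)
    dos <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    biallelic <- !grepl(",", vcfR::getALT(v))
    if (any(!biallelic))
      message(sprintf("skipping %d non-biallelic VCF records",
                      sum(!biallelic)))
    gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
    sep <- gsub("[01.]", "", gt[1, 1])
    count_alt <- function(g) {
      ifelse(is.na(g) | grepl("\\.", g),
             NA_real_,
             vapply(strsplit(g, "[/|]"),
                    function(a) sum(a == "1"), 0))
    }
    dos <- t(apply(gt, 2L, count_alt))
    colnames(dos) <- rownames(gt)
    ids <- rownames(dos)
  }
  storage.mode(dos) <- "double"
  bad <- !(dos %in% c(0, 1, 2) | is.na(dos))
  if (format == "tsv" && any(bad))
    stop("tsv dosages outside {0,1,2}")
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message(sprintf("imputing %d missing genotypes to the rounded mean dosage",
                    n_missing))
    for (j in which(colSums(is.na(dos)) > 0)) {
      fill <- round(mean(dos[, j], na.rm = TRUE))
      dos[is.na(dos[, j]), j] <- if (is.finite(fill)) fill else 0
    }
  }
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids
  if (is.null(map)) {
    m <- ncol(dos)
    map <- list(n_chromosomes = 1L, chrom_length_cM = m,
                loci = data.frame(id = colnames(dos) %||%
                                    sprintf("L%05d", seq_len(m)),
                                  chrom = 1L, pos_cM = seq_len(m) - 0.5,
                                  type = "snp"))
    class(map) <- "genome_map"
  }
  colnames(dos) <- map$loci$id
  new_genotype_matrix(dos, map)
}

#' Drop markers below a minor-allele-frequency threshold
#'
#' @param geno a `genotype_matrix`.
#' @param maf threshold; markers with `min(p, 1-p) < maf` are removed.
#' @return a filtered `genotype_matrix` (frequencies recomputed).
#' @export
filter_maf <- function(geno, maf = 0.05) {
  keep <- which(pmin(geno$p, 1 - geno$p) >= maf)
  if (!length(keep)) stop("no markers pass the MAF filter")
  subset_genotypes(geno, loci = keep)
}

#' Write / read a pedigree as 5-column CSV
#'
#' Columns `id, sire, dam, sex, generation`; `0` marks an unknown
#' parent. On reading, rows are re-ordered parents-before-offspring if
#' needed; cyclic pedigrees raise an error naming the offending ids.
#'
#' @param pedigree a `pedigree`.
#' @param path file path.
#' @return `path` invisibly (writer); a `pedigree` (reader).
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(as.data.frame(pedigree), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",",
                   colClasses = c("character", "character", "character",
                                  "character", "integer"))
  ord <- pedigree_order(df)
  new_pedigree(df[ord, , drop = FALSE])
}

#' Write / read phenotypes and true genetic values as TSV
#'
#' Missing phenotypes are written as `NA` and survive the round trip.
#'
#' @param phe a `phenotype_set`.
#' @param path file path.
#' @return `path` invisibly (writer); a `phenotype_set` (reader).
#' @export
write_phenotypes <- function(phe, path) {
  df <- data.frame(id = names(phe$y), y = phe$y, g_true = phe$g_true,
                   additive = phe$components$additive,
                   dominance = phe$components$dominance,
                   epistasis = phe$components$epistasis)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", rep("numeric", 5)))
  nm <- df$id
  structure(list(
    y = stats::setNames(df$y, nm),
    g_true = stats::setNames(df$g_true, nm),
    components = list(additive = stats::setNames(df$additive, nm),
                      dominance = stats::setNames(df$dominance, nm),
                      epistasis = stats::setNames(df$epistasis, nm)),
    sigma2_eps = NA_real_), class = "phenotype_set")
}

#' Write / read a kernel as a flat TSV (ids + dense matrix)
#'
#' @param K a `kernel_matrix`.
#' @param path file path.
#' @param kind kernel tag to restore on reading.
#' @return `path` invisibly (writer); a `kernel_matrix` (reader).
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(id = rownames(K$values), K$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, kind = "unknown") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(M) <- list(as.character(df[[1L]]), colnames(M))
  new_kernel_matrix(M, kind)
}

#' Write / read unit assignments as two-column TSV (id, unit)
#'
#' @param assignment a `unit_assignment`.
#' @param path file path.
#' @return `path` invisibly (writer); a `unit_assignment` (reader).
#' @export
write_units <- function(assignment, path) {
  df <- data.frame(id = names(assignment$unit), unit = assignment$unit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character")
  new_unit_assignment(stats::setNames(df$unit, df$id), NA_real_)
}

#' Load an experiment configuration from YAML
#'
#' An empty (or absent) file yields the full default configuration; any
#' present keys override the defaults and are schema-validated, with
#' every violation listed at once.
#'
#' @param path YAML file (or `NULL` for pure defaults).
#' @param profile base profile passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
load_config <- function(path = NULL, profile = "reduced") {
  over <- list()
  if (!is.null(path) && file.exists(path)) {
    over <- yaml::read_yaml(path)
    if (is.null(over)) over <- list()
  }
  if (!is.null(over$profile)) {
    profile <- over$profile
    over$profile <- NULL
  }
  base <- experiment_config(profile)
  probs <- character(0)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    probs <- c(probs, paste("unknown keys:", paste(bad, collapse = ", ")))
  check_rng <- function(key, lo, hi) {
    if (!is.null(over[[key]]) &&
        any(over[[key]] < lo | over[[key]] > hi))
      probs <<- c(probs, sprintf("%s must lie in [%g, %g]", key, lo, hi))
  }
  check_rng("rates", 0, 0.5)
  check_rng("H2", 1e-6, 1 - 1e-6)
  check_rng("mutation_rate", 0, 1)
  if (!is.null(over$gene_action) &&
      !all(over$gene_action %in% c("AD", "ADE", "PE")))
    probs <- c(probs, "gene_action must be among AD, ADE, PE")
  if (length(probs))
    stop("invalid configuration:\n  ", paste(probs, collapse = "\n  "))
  do.call(experiment_config, c(list(profile = profile), over))
}

#' Save a configuration to YAML
#' @param config an `experiment_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration (and its hash), the master seed and
#' package/R versions: everything needed to re-run bit-for-bit.
#'
#' @param config an `experiment_config`.
#' @param seed master seed of the run.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  cfg_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(cfg_yaml),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("genoconnect")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
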