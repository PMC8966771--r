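#' Read a plot-level phenotype table
#'
#' Expects a CSV with columns `plot_id`, `genotype_id`, `year`, `treatment`,
#' `block`, `date` (ISO-8601) and `gf`. Malformed rows fail loudly with row
#' numbers: green fractions outside `[0, 1]`, unparseable dates and duplicate
#' (plot, date) records are all rejected.
#'
#' @param path CSV file path.
#' @return Tibble with the input columns plus `environment_id`
#'   (`"<year>-<treatment>"`).
#' @export
read_phenotypes <- function(path) {
  req <- c("plot_id", "genotype_id", "year", "treatment", "block", "date",
           "gf")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("phenotype file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$gf <- suppressWarnings(as.numeric(df$gf))
  bad_gf <- which(is.na(df$gf) | df$gf < 0 | df$gf > 1)
  if (length(bad_gf)) {
    stop("green fraction outside [0, 1] (or non-numeric) at row(s): ",
         paste(utils::head(bad_gf, 10), collapse = ", "), call. = FALSE)
  }
  parsed <- as.Date(df$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(parsed))
  if (length(bad_date)) {
    stop("unparseable date at row(s): ",
         paste(utils::head(bad_date, 10), collapse = ", "), call. = FALSE)
  }
  df$date <- parsed
  dup <- duplicated(df[c("plot_id", "date")])
  if (any(dup)) {
    stop("duplicate (plot_id, date) at row(s): ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }
  df |>
    dplyr::mutate(year = as.integer(.data$year),
                  environment_id = paste(.data$year, .data$treatment,
                                         sep = "-")) |>
    tibble::as_tibble()
}

#' Read a daily temperature table
#'
#' CSV with columns `environment_id`, `date` (ISO-8601), `tmean_c`; the first
#' date of each environment is its sowing date.
#'
#' @param path CSV file path.
#' @return Tibble `environment_id`, `date`, `tmean_c`.
#' @export
read_temperatures <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  req <- c("environment_id", "date", "tmean_c")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("temperature file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$tmean_c <- suppressWarnings(as.numeric(df$tmean_c))
  if (anyNA(df$tmean_c)) stop("non-numeric tmean_c values", call. = FALSE)
  parsed <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(parsed)) stop("unparseable temperature dates", call. = FALSE)
  df$date <- parsed
  tibble::as_tibble(df[req])
}

#' Attach growing degree days to phenotype observations
#'
#' Computes per-environment thermal time from the daily temperature record
#' and joins `day` (days after sowing) and `gdd` onto each observation by
#' date. Observations on dates outside the temperature record fail.
#'
#' @param pheno Phenotype tibble ([read_phenotypes()]).
#' @param temps Temperature tibble ([read_temperatures()]).
#' @param base_temp Base temperature for degree-day accumulation.
#' @return The phenotype tibble with `day` and `gdd` columns added.
#' @export
attach_gdd <- function(pheno, temps, base_temp = 8) {
  if (!"environment_id" %in% names(pheno)) {
    stopifnot(all(c("year", "treatment") %in% names(pheno)))
    pheno$environment_id <- paste(pheno$year, pheno$treatment, sep = "-")
  }
  tt <- thermal_time(temps, base_temp)
  out <- dplyr::left_join(pheno, tt[c("environment_id", "date", "day", "gdd")],
                          by = c("environment_id", "date"))
  if (anyNA(out$gdd)) {
    stop("observation dates missing from the temperature record for: ",
         paste(utils::head(unique(
           out$environment_id[is.na(out$gdd)]), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read biallelic genotypes from a VCF
#'
#' Parses GT fields with the vcfR package, drops multiallelic records (count
#' reported), and codes calls as -1 (reference homozygote), 0 (heterozygote,
#' phased or unphased), 1 (alternative homozygote), `NA` missing.
#'
#' @param path VCF file path.
#' @return Coded matrix, genotypes x markers.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    message("dropped ", sum(multi), " multiallelic record(s)")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- -1
    out[x %in% c("0/1", "1/0")] <- 0
    out[x %in% c("1/1")] <- 1
    out
  }
  m <- apply(gt, 2, code)
  rownames(m) <- rownames(gt)
  t(m)  # genotypes x markers
}

#' Read coded genotypes from CSV
#'
#' Alternative to VCF input: a CSV with a `genotype_id` column and one
#' column per marker holding -1/0/1 codes (empty or NA for missing).
#'
#' @param path CSV file path.
#' @return Coded matrix, genotypes x markers.
#' @export
read_genotypes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"genotype_id" %in% names(df)) {
    stop("coded genotype CSV needs a `genotype_id` column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "genotype_id")])
  if (!is.numeric(m)) stop("marker columns must be numeric", call. = FALSE)
  bad <- !(m %in% c(-1, 0, 1, NA))
  if (any(bad)) {
    stop("marker codes must be -1, 0, 1 or missing", call. = FALSE)
  }
  rownames(m) <- df$genotype_id
  m
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits one biallelic SNP record per marker with GT-only FORMAT, suitable
#' for round-tripping through [read_genotypes_vcf()].
#'
#' @param geno Coded marker matrix (genotypes x markers, -1/0/1/NA).
#' @param path Output file.
#' @export
write_genotypes_vcf <- function(geno, path) {
  gt_code <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno)), function(j) {
    calls <- gt_code[as.character(geno[, j])]
    calls[is.na(calls)] <- "./."
    paste(c("1", j, colnames(geno)[j], "A", "T", ".", "PASS", ".", "GT",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a CSV with a reproducibility sidecar
#'
#' Alongside `<path>`, writes `<path>.meta.json` recording the output hash,
#' input-file hashes, the seed and any configuration supplied — enough to
#' reproduce the file.
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param seed Seed used to produce the data, if any.
#' @param config Configuration list echoed into the sidecar.
#' @param inputs Character vector of input file paths to hash.
#' @export
write_csv_with_meta <- function(df, path, seed = NULL, config = NULL,
                                inputs = character()) {
  readr::write_csv(df, path)
  meta <- list(
    file = basename(path),
    md5 = unname(tools::md5sum(path)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write / read a genomic relationship matrix as CSV
#'
#' Stored with a header row and a leading `genotype_id` column.
#' @param grm GRM matrix.
#' @param path CSV path.
#' @export
write_grm <- function(grm, path) {
  df <- tibble::as_tibble(grm, rownames = "genotype_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$genotype_id
  m
}

#' Export a simulated study to disk
#'
#' Writes the phenotype and temperature CSVs (with metadata sidecars), the
#' genotypes as VCF, and the simulation ground truth as JSON, in exactly the
#' formats the readers of this package consume.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config[c("n_genotypes", "n_markers", "n_blocks", "nu",
                        "plot_jitter_sd", "seed")]
  pheno_out <- study$pheno[c("plot_id", "genotype_id", "year", "treatment",
                             "block", "date", "gf")]
  write_csv_with_meta(pheno_out, file.path(dir, "phenotypes.csv"),
                      seed = study$config$seed, config = cfg)
  write_csv_with_meta(study$temps, file.path(dir, "temperatures.csv"),
                      seed = study$config$seed, config = cfg)
  write_genotypes_vcf(study$geno, file.path(dir, "genotypes.vcf"))
  truth <- list(
    config = cfg,
    env_means = study$truth$env_means,
    params = study$truth$params
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a fitted dynamics parameter table
#'
#' @param fits A [fit_dynamics()] result.
#' @param path CSV path.
#' @param ... Passed to [write_csv_with_meta()].
#' @export
write_dynamics_fit <- function(fits, path, ...) {
  write_csv_with_meta(dplyr::as_tibble(fits), path, ...)
}
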