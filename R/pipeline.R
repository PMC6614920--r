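# End-to-end orchestration: read assay tables, fit, join with the
# free-energy calculus, and emit the standard report bundle.

#' Read a gel-shift titration CSV
#'
#' UTF-8, comma-separated, header row mandatory. Required columns:
#' `construct_id`, `replicate_id`, `mg_mM`, `temperature_K`, `fa_uM`,
#' `M0_nM`, and either `fD` or `monomer_intensity` + `dimer_intensity`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "replicate_id", "mg_mM", "temperature_K",
            "fa_uM", "M0_nM")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Read a lead-cleavage intensity CSV
#'
#' Required columns: `construct_id`, `mg_mM`, `temperature_K`, `fa_uM`,
#' `M0_nM`, `position`, `intensity`, `direction`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cleavage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "mg_mM", "temperature_K", "fa_uM", "M0_nM",
            "position", "intensity", "direction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Count constructs passing a Kd threshold
#'
#' Reproduces summary tallies of the form "N constructs with Kd below
#' 100 nM" on any Kd table. Threshold comparisons are inclusive for
#' `"<="`/`">="` and exclusive for `"<"`/`">"`; rows flagged
#' `no_assembly` (when the column exists) are excluded.
#'
#' @param kd_table data.frame with a `Kd_nM` column.
#' @param op one of `"<="`, `"<"`, `">="`, `">"`.
#' @param threshold_nM threshold, nM.
#' @return integer count.
#' @export
query_report <- function(kd_table, op = c("<=", "<", ">=", ">"),
                         threshold_nM) {
  op <- match.arg(op)
  if (!"Kd_nM" %in% names(kd_table)) stop("kd_table lacks a Kd_nM column")
  kd <- kd_table$Kd_nM
  if ("no_assembly" %in% names(kd_table)) kd <- kd[!kd_table$no_assembly]
  kd <- kd[is.finite(kd)]
  sum(do.call(op, list(kd, threshold_nM)))
}

fa_response_table <- function(kd_table) {
  base_cols <- c("construct_id", "assay", "mg_mM", "temperature_K")
  minus <- kd_table[kd_table$fa_uM == 0, , drop = FALSE]
  plus <- kd_table[kd_table$fa_uM > 0, , drop = FALSE]
  if (nrow(minus) == 0L || nrow(plus) == 0L)
    return(data.frame())
  merged <- merge(minus, plus, by = base_cols, suffixes = c("_minusFA", "_plusFA"))
  if (nrow(merged) == 0L) return(data.frame())
  usable <- !(merged$no_assembly_minusFA | merged$no_assembly_plusFA)
  data.frame(
    merged[base_cols],
    Kd_minusFA_nM = merged$Kd_nM_minusFA,
    Kd_plusFA_nM = merged$Kd_nM_plusFA,
    fold_change = ifelse(usable,
                         fold_change(merged$Kd_nM_minusFA, merged$Kd_nM_plusFA),
                         NA_real_),
    ddG_FA_kcal_mol = ifelse(usable,
                             ddg_fa(merged$Kd_nM_plusFA, merged$Kd_nM_minusFA,
                                    merged$temperature_K),
                             NA_real_),
    stringsAsFactors = FALSE
  )
}

write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Fits every assay table named in the configuration, joins the results
#' with the free-energy calculus, and writes the report bundle into
#' `outdir`: `kd_table.csv` (per construct x condition), `ddg_ledger.csv`
#' (dG and ddG versus the reference construct, sorted ddG ascending with
#' flagged constructs carrying bound markers instead of energies),
#' `fa_response.csv` (Kd with/without ligand, fold change, ddG_FA),
#' `signature_report.tsv` (families, pair classes, distances) when a
#' variant FASTA is supplied, and `run_manifest.json`. Re-running with the
#' same configuration and seed reproduces the bundle byte for byte.
#'
#' Fit failures are isolated: the failing construct group is dropped from
#' the tables and recorded in the manifest's `failures` field.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `gelshift_input`, `lead_input` (CSV paths), `fasta` (variant FASTA),
#'   `reference_construct` (default `"4LVV"`), `compute_ddg` (default
#'   `TRUE`), `detection_limit_nM` (default 1), `fold_threshold` (default
#'   1.5), `fix_beta`, `seed`, `outdir` (required).
#' @return invisibly, a list with the tables and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  reference <- config$reference_construct %||% "4LVV"
  compute_ddg <- config$compute_ddg %||% TRUE
  detection_limit <- config$detection_limit_nM %||% 1
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  failures <- character()
  kd_parts <- list()
  if (!is.null(config$gelshift_input)) {
    df <- read_titration_csv(config$gelshift_input)
    kd_parts$gelshift <- tryCatch(
      fit_gelshift_table(df, fix_beta = config$fix_beta,
                         detection_limit_nM = detection_limit),
      error = function(e) {
        failures <<- c(failures, paste0("gelshift: ", conditionMessage(e)))
        NULL
      })
  }
  if (!is.null(config$lead_input)) {
    df <- read_cleavage_csv(config$lead_input)
    kd_parts$lead <- tryCatch(
      fit_lead_table(df, detection_limit_nM = detection_limit),
      error = function(e) {
        failures <<- c(failures, paste0("lead: ", conditionMessage(e)))
        NULL
      })
  }
  kd_table <- do.call(rbind, kd_parts)
  if (is.null(kd_table) || nrow(kd_table) == 0L)
    stop("no assay input produced any fit")
  rownames(kd_table) <- NULL

  if (compute_ddg && !reference %in% kd_table$construct_id)
    stop("reference construct '", reference,
         "' absent from the fitted constructs; set compute_ddg: false or ",
         "fix the configuration")

  ledger <- thermo_table(kd_table, reference_construct = reference)
  flagged <- ledger$no_assembly | ledger$below_detection
  ledger$bound_marker <- ifelse(
    ledger$no_assembly, paste0("Kd > ", signif(ledger$Kd_nM, 3), " nM"),
    ifelse(ledger$below_detection,
           paste0("Kd < ", ledger$detection_limit_nM %||% detection_limit, " nM"), ""))
  ledger$dG_kcal_mol[flagged] <- NA_real_
  ledger$ddG_kcal_mol[flagged] <- NA_real_
  ledger <- ledger[order(is.na(ledger$ddG_kcal_mol), ledger$ddG_kcal_mol), ,
                   drop = FALSE]

  fa_resp <- fa_response_table(kd_table)

  paths <- list(
    kd_table = write_report_csv(kd_table, file.path(outdir, "kd_table.csv")),
    ddg_ledger = write_report_csv(ledger, file.path(outdir, "ddg_ledger.csv")),
    fa_response = write_report_csv(fa_resp, file.path(outdir, "fa_response.csv"))
  )

  sig_report <- NULL
  if (!is.null(config$fasta)) {
    variants <- read_signature_fasta(config$fasta)
    sig_report <- signature_report(variants, reference = reference)
    sig_report$consensus <- as.character(consensus(variants))
    paths$signature_report <- file.path(outdir, "signature_report.tsv")
    utils::write.table(sig_report, paths$signature_report, sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  manifest <- list(
    package = "tectofit",
    version = as.character(utils::packageVersion("tectofit")),
    reference_construct = reference,
    seed = config$seed %||% NA,
    config = config,
    config_md5 = unname(tools::md5sum(
      local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
    failures = failures,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(kd_table = kd_table, ddg_ledger = ledger,
                 fa_response = fa_resp, signature_report = sig_report,
                 failures = failures, paths = c(paths, manifest = manifest_path)))
}
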