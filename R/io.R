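# Shared I/O: one declared CSV dialect (concentrations in uM, times in s,
# temperatures in degC, rate constants in M^-1 s^-1), converted to mol/L
# internally at the boundary.

# validate columns and collect row-level errors with line numbers
check_schema <- function(df, path, required, nonneg = character()) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  errs <- character()
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (length(bad)) {
      errs <- c(errs, sprintf("line %d: column '%s' is missing or unparsable",
                              bad + 1L, col))
    }
  }
  for (col in nonneg) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      errs <- c(errs, sprintf("line %d: column '%s' is negative (%g)",
                              bad + 1L, col, df[[col]][bad]))
    }
  }
  if (length(errs)) {
    stop("schema errors in '", path, "':\n  ", paste(errs, collapse = "\n  "))
  }
  invisible(df)
}

#' Read a densitometry lane table
#'
#' CSV with columns `condition`, `oxidant_conc_uM`, `time_s`, `temperature_C`,
#' `monomer`, `dimer` (order-insensitive). Concentrations are converted to
#' mol/L; rows with missing or negative values are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @return data.frame with columns `condition`, `oxidant_conc` (mol/L),
#'   `time_s`, `temperature_C`, `monomer`, `dimer`.
#' @export
read_densitometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, path,
               required = c("condition", "oxidant_conc_uM", "time_s",
                            "temperature_C", "monomer", "dimer"),
               nonneg = c("oxidant_conc_uM", "time_s", "monomer", "dimer"))
  data.frame(condition = df$condition,
             oxidant_conc = df$oxidant_conc_uM * 1e-6,
             time_s = df$time_s, temperature_C = df$temperature_C,
             monomer = df$monomer, dimer = df$dimer)
}

#' Write a densitometry lane table
#'
#' Inverse of [read_densitometry()] (mol/L back to the uM file dialect).
#'
#' @param lanes data.frame as returned by [read_densitometry()] or
#'   [gen_blot_timecourse()].
#' @param path File path.
#' @export
write_densitometry <- function(lanes, path) {
  out <- data.frame(condition = lanes$condition,
                    oxidant_conc_uM = lanes$oxidant_conc * 1e6,
                    time_s = lanes$time_s,
                    temperature_C = lanes$temperature_C,
                    monomer = lanes$monomer, dimer = lanes$dimer)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a progression curve with its metadata header
#'
#' File format: comment lines `# key: value` carrying `enzyme_conc_nM`,
#' `gsh_mM`, `rooh0_uM`, `path_cm`, followed by a CSV body with columns
#' `time_s`, `a340`.
#'
#' @param path File path.
#' @return data.frame `time_s`, `a340` with attributes `enzyme_conc`,
#'   `gsh_conc`, `rooh0` (mol/L) and `path_cm`.
#' @export
read_progression_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  need <- c("enzyme_conc_nM", "gsh_mM", "rooh0_uM", "path_cm")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("progression-curve header in '", path, "' is missing: ",
         paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  check_schema(df, path, required = c("time_s", "a340"), nonneg = "time_s")
  structure(df[c("time_s", "a340")],
            enzyme_conc = meta$enzyme_conc_nM * 1e-9,
            gsh_conc = meta$gsh_mM * 1e-3,
            rooh0 = meta$rooh0_uM * 1e-6,
            path_cm = meta$path_cm)
}

#' Write a progression curve with its metadata header
#'
#' @param curve data.frame from [gen_progression_curve()] or
#'   [read_progression_curve()] (attributes carry the metadata).
#' @param path File path.
#' @export
write_progression_curve <- function(curve, path) {
  hdr <- c(sprintf("# enzyme_conc_nM: %.10g", attr(curve, "enzyme_conc") * 1e9),
           sprintf("# gsh_mM: %.10g", attr(curve, "gsh_conc") * 1e3),
           sprintf("# rooh0_uM: %.10g", attr(curve, "rooh0") * 1e6),
           sprintf("# path_cm: %.10g", attr(curve, "path_cm")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time_s = curve$time_s, a340 = curve$a340),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an endpoint-assay table
#'
#' CSV with columns `assay`, `absorbance`, `blank`, `path_cm`, `dilution`;
#' `assay` must match a species label in [extinction_coefficients()].
#'
#' @param path File path.
#' @return Input data.frame with an added `conc_M` column from
#'   [conc_from_absorbance()].
#' @export
read_endpoint_assays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, path,
               required = c("assay", "absorbance", "blank", "path_cm",
                            "dilution"),
               nonneg = c("absorbance", "blank"))
  df$conc_M <- mapply(function(a, b, p, d, lab) {
    conc_from_absorbance(a, epsilon = lab, blank = b, path_cm = p,
                         dilution = d)
  }, df$absorbance, df$blank, df$path_cm, df$dilution, df$assay)
  df
}

#' Read a native-MS peak table
#'
#' CSV with columns `ligand`, `charge`, `species` (`P` for unbound, `PL` for
#' bound), `area`. All `P` rows are shared across ligands.
#'
#' @param path File path.
#' @param p0 Total protein concentration, mol/L.
#' @param l0 Named (by ligand) or unnamed vector of total ligand
#'   concentrations, mol/L.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, p0, l0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, path, required = c("ligand", "charge", "species", "area"),
               nonneg = "area")
  if (!all(df$species %in% c("P", "PL"))) {
    stop("column 'species' must be 'P' or 'PL'")
  }
  charges <- sort(unique(df$charge))
  p_rows <- df[df$species == "P", ]
  unbound <- vapply(charges, function(z) sum(p_rows$area[p_rows$charge == z]),
                    numeric(1))
  ligs <- sort(unique(df$ligand[df$species == "PL"]))
  bound <- sapply(ligs, function(lg) {
    vapply(charges, function(z) {
      sum(df$area[df$species == "PL" & df$ligand == lg & df$charge == z])
    }, numeric(1))
  })
  if (is.null(dim(bound))) bound <- matrix(bound, nrow = length(charges))
  if (!is.null(names(l0))) l0 <- l0[ligs]
  peak_set(charge_states = charges, unbound_areas = unbound,
           bound_areas = bound, p0 = p0, l0 = l0, ligands = ligs)
}

#' Run a configured analysis pipeline
#'
#' Thin orchestrator over the analysis stages. The configuration is a named
#' list (or a YAML file path parsed with \pkg{yaml}) with an optional global
#' `seed`, an `outdir`, and a `stages` list. Supported stages:
#'
#' * `blot`: `input` (densitometry CSV) and optional `enzyme_conc_uM`;
#'   runs [blot_rate_constant()].
#' * `dalziel`: `inputs` (progression-curve CSV paths); runs
#'   [substrate_trace()], [dalziel_points()] and [dalziel_fit()].
#' * `competition`: `fraction`, `k_ref`, `ref_conc_uM`, `comp_conc_uM`,
#'   `monitored`; runs [competitor_k_from_suppression()].
#' * `native_ms`: `input` (peak CSV), `p0_uM`, `l0_uM`; runs
#'   [kd_from_areas()].
#'
#' Per-stage results are written as CSV under `outdir` together with a
#' `summary.csv` of all inferred constants (stable row order), and returned
#' invisibly.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with per-stage results and the summary
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$stages))
  known <- c("seed", "outdir", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  outdir <- config$outdir %||% tempdir()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  results <- list()
  summary_rows <- list()
  for (nm in names(config$stages)) {
    st <- config$stages[[nm]]
    res <- tryCatch(switch(nm,
      blot = {
        lanes <- read_densitometry(st$input)
        k <- blot_rate_constant(lanes,
               enzyme_conc = (st$enzyme_conc_uM %||% NA_real_) * 1e-6)
        utils::write.csv(k$details$per_conc,
                         file.path(outdir, "blot_per_conc.csv"),
                         row.names = FALSE)
        k
      },
      dalziel = {
        pts <- do.call(rbind, lapply(st$inputs, function(p) {
          cv <- read_progression_curve(p)
          tr <- substrate_trace(cv$time_s, cv$a340, rooh0 = attr(cv, "rooh0"),
                                path_cm = attr(cv, "path_cm"))
          dalziel_points(tr$time_s, tr$conc,
                         enzyme_conc = attr(cv, "enzyme_conc"),
                         gsh_conc = attr(cv, "gsh_conc"))
        }))
        dalziel_fit(pts$enzyme_conc, pts$v0, pts$rooh_conc, pts$gsh_conc)
      },
      competition = {
        competitor_k_from_suppression(st$fraction, k_ref = st$k_ref,
          ref_conc = st$ref_conc_uM * 1e-6,
          comp_conc = st$comp_conc_uM * 1e-6,
          monitored = st$monitored %||% "competitor")
      },
      native_ms = {
        pk <- read_peaks(st$input, p0 = st$p0_uM * 1e-6,
                         l0 = st$l0_uM * 1e-6)
        kd_from_areas(pk)
      },
      stop("unknown stage '", nm, "'")),
      error = function(e) {
        stop("stage '", nm, "' failed: ", conditionMessage(e))
      })
    results[[nm]] <- res
    summary_rows[[nm]] <- stage_summary_rows(nm, res)
  }
  summary <- do.call(rbind, summary_rows[order(names(summary_rows))])
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  results$summary <- summary
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_summary_rows <- function(stage, res) {
  if (inherits(res, "rate_constant")) {
    data.frame(stage = stage, quantity = "k", value = res$value,
               se = res$se, units = res$units,
               temperature_C = res$temperature,
               flags = paste(res$flags, collapse = ";"))
  } else if (inherits(res, "dalziel_fit")) {
    data.frame(stage = stage,
               quantity = c("k_plus1", "k_plus2"),
               value = c(res$k_plus1, res$k_plus2),
               se = c(res$k_plus1_se, res$k_plus2_se),
               units = "M^-1 s^-1", temperature_C = NA_real_,
               flags = paste(res$flags, collapse = ";"))
  } else if (inherits(res, "binding_result")) {
    data.frame(stage = stage,
               quantity = paste0("Kd_", names(res$kd)),
               value = unname(res$kd), se = NA_real_, units = "M",
               temperature_C = NA_real_, flags = unname(res$flags))
  } else {
    data.frame(stage = stage, quantity = "value", value = NA_real_,
               se = NA_real_, units = "", temperature_C = NA_real_,
               flags = "unsummarized")
  }
}
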