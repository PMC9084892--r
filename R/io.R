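## required / optional columns per modality schema
.schemas <- list(
  urea = list(required = c("construct", "urea_M", "fir"),
              optional = character(0)),
  thermal = list(required = c("construct", "temp_C", "fir"),
                 optional = "backscatter"),
  bli = list(required = c("construct", "nacl_mM", "conc_M", "time_s",
                          "response", "phase", "well_role"),
             optional = character(0)),
  itc = list(required = c("injection_index", "heat_kcal"),
             optional = c("construct", "heat_error_kcal")),
  hdx = list(required = c("construct", "pep_start", "pep_end",
                          "pep_sequence", "timepoint_s", "replicate",
                          "uptake_Da"),
             optional = character(0))
)

#' Load a modality table from CSV/TSV
#'
#' Reads a comma- or tab-separated table (UTF-8, header row mandatory,
#' `.` decimal) and validates it against the named modality schema.
#' Missing required columns are a failure that names them; unknown columns
#' are preserved with a warning; row order is preserved.
#'
#' @param path Path to a CSV or TSV file.
#' @param schema One of `"urea"`, `"thermal"`, `"bli"`, `"itc"`, `"hdx"`.
#' @return An object of class `"dataset_bundle"`: a list with `modality`,
#'   `table` (data.frame), `metadata` (construct labels present) and
#'   `provenance` (source path, schema version).
#' @export
load_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           check.names = FALSE)
  sc <- .schemas[[schema]]
  miss <- setdiff(sc$required, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(tab), c(sc$required, sc$optional))
  if (length(extra) > 0L) {
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  labels <- if ("construct" %in% names(tab)) unique(tab$construct) else NULL
  structure(list(modality = schema, table = tab,
                 metadata = list(constructs = labels),
                 provenance = list(source = path, schema_version = "1.0")),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %s: %d rows from %s\n", x$modality,
              nrow(x$table), x$provenance$source))
  invisible(x)
}

#' Unfolding curves from a dataset bundle
#'
#' @param bundle A `"urea"` [load_table()] bundle.
#' @param temperature Kelvin (default 293.15).
#' @return A list of [unfolding_curve()] objects, one per construct.
#' @export
curves_from_bundle <- function(bundle, temperature = 293.15) {
  stopifnot(inherits(bundle, "dataset_bundle"), bundle$modality == "urea")
  lapply(split(bundle$table, bundle$table$construct), function(d) {
    unfolding_curve(d$construct[1L], d$urea_M, d$fir, temperature)
  })
}

#' Sensorgrams from a dataset bundle
#'
#' Reconstructs [sensorgram()] objects from long-format BLI data. Rows
#' with `phase` `assoc` or `dissoc` define the phase windows; `well_role`
#' separates sample wells from reference wells.
#'
#' @param bundle A `"bli"` [load_table()] bundle.
#' @return A nested list: per (construct, nacl, conc) a list with
#'   `sample`, `internal_ref`, `parallel_ref`, `parallel_internal_ref`
#'   ([sensorgram()] or `NULL`).
#' @export
sensorgrams_from_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"), bundle$modality == "bli")
  tab <- bundle$table
  key <- interaction(tab$construct, tab$nacl_mM, tab$conc_M, drop = TRUE)
  lapply(split(tab, key), function(d) {
    out <- list()
    for (role in unique(d$well_role)) {
      w <- d[d$well_role == role, ]
      w <- w[order(w$time_s), ]
      aw <- range(w$time_s[w$phase == "assoc"])
      dw <- range(w$time_s[w$phase == "dissoc"])
      out[[role]] <- sensorgram(w$construct[1L], w$conc_M[1L], w$time_s,
                                w$response, aw, dw, nacl = w$nacl_mM[1L])
    }
    names(out)[names(out) == "sample"] <- "sample"
    out
  })
}

## strip classes recursively so jsonlite serializes plain lists
.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .unclass_deep)
  } else x
}

#' Write an analysis result to CSV or JSON
#'
#' JSON serialization keeps full double precision (no digit rounding), so
#' re-reading reproduces every numeric field; CSV output requires a
#' data.frame (use [fit_report_table()] for fit objects). Writing an empty
#' result produces a valid empty document with a warning.
#'
#' @param results A fit object, list, or data.frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `invisible(path)`.
#' @export
write_report <- function(results, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write to nonexistent directory: ", dir, call. = FALSE)
  }
  if ((is.data.frame(results) && nrow(results) == 0L) ||
      (!is.data.frame(results) && length(results) == 0L)) {
    warning("writing an empty result document", call. = FALSE)
  }
  if (format == "csv") {
    if (!is.data.frame(results)) {
      stop("CSV output requires a data.frame; see fit_report_table()",
           call. = FALSE)
    }
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(.unclass_deep(results), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Flat parameter table for a fit object
#'
#' One row per (parameter, construct) with value and standard error --
#' the CSV mirror of a fit report.
#'
#' @param fit A `three_state_fit`, `one_site_fit` or
#'   `one_site_thermo_fit`.
#' @return A data.frame with columns `parameter`, `value`, `stderr`,
#'   `construct`.
#' @export
fit_report_table <- function(fit) {
  if (inherits(fit, "three_state_fit")) {
    sh <- data.frame(parameter = names(fit$shared),
                     value = unlist(fit$shared),
                     stderr = unlist(fit$se_shared),
                     construct = "(shared)", stringsAsFactors = FALSE)
    pc <- do.call(rbind, lapply(seq_len(nrow(fit$per_construct)), function(i) {
      r <- fit$per_construct[i, ]
      data.frame(
        parameter = c("bN", "bI", "bD", "dG_I0", "dG_D0", "dG_IN",
                      "c_urea_IN"),
        value = c(r$bN, r$bI, r$bD, r$dG_I0, r$dG_D0, r$dG_IN, r$c_urea_IN),
        stderr = c(r$bN_se, r$bI_se, r$bD_se, r$dG_I0_se, r$dG_D0_se,
                   r$dG_IN_se, NA),
        construct = r$construct, stringsAsFactors = FALSE)
    }))
    out <- rbind(sh, pc)
  } else if (inherits(fit, "one_site_fit")) {
    out <- data.frame(
      parameter = c("kon", "koff", "kd", paste0("rmax_", names(fit$rmax))),
      value = c(fit$kon, fit$koff, fit$kd, unname(fit$rmax)),
      stderr = c(fit$kon * fit$rel_se[["kon"]],
                 fit$koff * fit$rel_se[["koff"]],
                 NA, rep(NA, length(fit$rmax))),
      construct = NA_character_, stringsAsFactors = FALSE)
  } else if (inherits(fit, "one_site_thermo_fit")) {
    th <- fit$thermo
    out <- data.frame(
      parameter = c("n", "ka", "dh", "kd", "dg", "tds", "offset"),
      value = c(th$n, th$ka, th$dh, th$kd, th$dg, th$tds, fit$offset),
      stderr = c(fit$se[["n"]], fit$se[["ka"]], fit$se[["dh"]], NA, NA, NA,
                 if ("offset" %in% names(fit$se)) fit$se[["offset"]] else NA),
      construct = NA_character_, stringsAsFactors = FALSE)
  } else {
    stop("unsupported fit object of class ", paste(class(fit), collapse = "/"),
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
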