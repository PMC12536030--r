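#' Read case records from JSONL
#'
#' One JSON object per line:
#' `{"case_id": str, "text": str|null, "image_probs": [k floats]|null,
#' "label": str|null}`. Invalid rows are reported with their line numbers;
#' in strict mode (default) any invalid row aborts the read, otherwise
#' offending rows are dropped with a warning.
#'
#' @param path File path.
#' @param strict Abort on the first batch of invalid rows (default TRUE).
#' @inheritParams validate_prob_vector
#' @return List of [case_record()]s.
#' @export
read_cases <- function(path, strict = TRUE, labels = retinal_labels()) {
  read_jsonl(path, strict, function(row, lineno) {
    case_record(case_id = row$case_id,
                text = row$text %||% NULL,
                image_probs = unlist(row$image_probs) %||% NULL,
                label = row$label %||% NULL,
                labels = labels)
  })
}

#' Write case records to JSONL
#'
#' Probabilities are serialized at full double precision; round-trips with
#' [read_cases()] losslessly.
#'
#' @param cases List of [case_record()]s.
#' @param path Destination file.
#' @export
write_cases <- function(cases, path) {
  write_jsonl(lapply(cases, function(x) {
    list(case_id = x$case_id, text = x$text, image_probs = x$image_probs,
         label = x$label)
  }), path)
}

#' Read submodel outputs from JSONL
#'
#' Rows are
#' `{"case_id", "submodel_id", "modality", "probs": [k]|null,
#' "response_lengths": [k]|null}`; at least one of `probs` and
#' `response_lengths` must be present (when only lengths are present the
#' distribution is derived through [lengths_to_distribution()]). Duplicate
#' `(case_id, submodel_id)` pairs are rejected.
#'
#' @inheritParams read_cases
#' @param cfg [confidence_config()] used when only lengths are present.
#' @return List of [submodel_output()]s.
#' @export
read_submodel_outputs <- function(path, strict = TRUE,
                                  cfg = confidence_config(),
                                  labels = retinal_labels()) {
  outputs <- read_jsonl(path, strict, function(row, lineno) {
    probs <- unlist(row$probs) %||% NULL
    lengths <- unlist(row$response_lengths) %||% NULL
    if (is.null(probs) && is.null(lengths)) {
      stop("one of probs/response_lengths is required", call. = FALSE)
    }
    if (is.null(probs)) {
      probs <- as.numeric(lengths_to_distribution(lengths, cfg, labels))
    }
    submodel_output(row$submodel_id, row$case_id, probs,
                    modality = row$modality %||% "text",
                    response_lengths = lengths, labels = labels)
  })
  keys <- vapply(outputs, function(o) paste(o$case_id, o$submodel_id), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (case_id, submodel_id) pair(s): ",
         paste(utils::head(unique(keys[duplicated(keys)]), 3L),
               collapse = "; "), call. = FALSE)
  }
  outputs
}

#' @rdname read_submodel_outputs
#' @param outputs List of [submodel_output()]s.
#' @param path Destination file.
#' @export
write_submodel_outputs <- function(outputs, path) {
  write_jsonl(lapply(outputs, function(x) {
    list(case_id = x$case_id, submodel_id = x$submodel_id,
         modality = x$modality, probs = x$probs,
         response_lengths = x$response_lengths)
  }), path)
}

#' Write / read a reliability profile as JSON
#'
#' Serialized as `{"alpha": {submodel: rate}, "n_calibration": n, "seed": s}`.
#'
#' @param profile A [reliability_profile()].
#' @param path File path.
#' @export
write_reliability_profile <- function(profile, path) {
  jsonlite::write_json(list(alpha = as.list(profile$alpha),
                            n_calibration = profile$n_calibration,
                            seed = profile$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_reliability_profile
#' @export
read_reliability_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  reliability_profile(unlist(x$alpha), n_calibration = x$n_calibration,
                      seed = x$seed %||% NA_integer_)
}

#' Write fused diagnoses (with optional triage actions) to JSONL
#'
#' Each row keeps the full per-submodel weight and entropy diagnostics for
#' auditability.
#'
#' @param fused Named list of `fused_diagnosis` objects (names = case_ids).
#' @param path Destination file.
#' @param actions Optional named list of `triage_action`s aligned to
#'   `fused`.
#' @export
write_fused_diagnoses <- function(fused, path, actions = NULL) {
  rows <- lapply(names(fused), function(id) {
    fd <- fused[[id]]
    row <- list(case_id = id, method = fd$method,
                probs = as.numeric(fd$probs),
                ranking = fd$ranking,
                per_submodel_weight = as.list(fd$per_submodel_weight),
                per_submodel_entropy = as.list(fd$per_submodel_entropy),
                contributing = fd$contributing)
    if (!is.null(actions)) {
      a <- actions[[id]]
      row$action <- a$action
      row$action_class <- if (is.na(a$class)) NULL else a$class
      row$action_probability <- if (is.na(a$probability)) NULL else
        a$probability
    }
    row
  })
  write_jsonl(rows, path)
}

#' Write an evaluation report as JSON (and optionally CSV)
#'
#' The report carries a reliability block (one rate per submodel on the
#' calibration subset) and a per-method metric block (one row per single
#' submodel plus the two fusion strategies), together with the seed and a
#' config hash for provenance. Numbers are stored at full precision; the CSV
#' export rounds to 4 decimals for display.
#'
#' @param report A report list as produced by [run_scenario()].
#' @param path Destination `.json` path.
#' @param csv_path Optional path for a flat CSV rendering of the metric
#'   block.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  out <- unclass(report)
  out$per_method <- lapply(out$per_method, function(row) {
    row$top_k <- as.list(row$top_k)
    row
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(csv_path)) {
    per <- report$per_method
    df <- do.call(rbind, lapply(names(per), function(m) {
      row <- per[[m]]
      data.frame(method = m,
                 as.list(round(unlist(row$top_k), 4)),
                 mrr = round(row$mrr, 4), ece = round(row$ece, 4),
                 brier = round(row$brier, 4), n = row$n,
                 check.names = FALSE)
    }))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(path)
}

# --- JSONL plumbing -------------------------------------------------------

read_jsonl <- function(path, strict, parse_row) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: '%s' (run the producing command first)",
                 path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  errors <- character(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch({
      row <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
      parse_row(row, i)
    }, error = function(e) {
      errors <<- c(errors, sprintf("line %d: %s", i, conditionMessage(e)))
      NULL
    })
    records[[i]] <- rec
  }
  if (length(errors) > 0L) {
    msg <- paste0(sprintf("%d invalid row(s) in '%s':\n", length(errors),
                          path),
                  paste(utils::head(errors, 10L), collapse = "\n"))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  Filter(Negate(is.null), records)
}

write_jsonl <- function(rows, path) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (row in rows) {
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               con, sep = "\n")
  }
  invisible(path)
}
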