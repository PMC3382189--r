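#' @title Screening reports and ablation experiments
#' @description Renders `screen_report` objects in the layout of classical
#'   pharmacophore screening tables (strain energy and fit RMSD of the
#'   best hit, conformer and hit counts, per-anchor hydrogen-bond distance
#'   and angle with borderline flags) and runs the excluded-volume /
#'   essential-TM5 ablation suite.
#' @name report
NULL

hb_cell <- function(hb, anchor) {
  if (is.null(hb)) return("")
  sub <- hb[hb$anchor == anchor, , drop = FALSE]
  if (!nrow(sub)) return("")
  cells <- vapply(seq_len(nrow(sub)), function(i) {
    lab <- if (sub$group[i] %in% c("m", "p"))
      paste0("*", sub$group[i], "*") else ""
    cell <- sprintf("%s%.1f(%.0f)", lab, sub$d[i], sub$angle[i])
    if (sub$verdict[i] != "ok") cell <- paste0("**", cell, "**")
    cell
  }, character(1))
  paste(cells, collapse = " ")
}

report_table <- function(report) {
  rows <- report$rows
  anchors <- unique(unlist(lapply(report$hbonds, function(h) h$anchor)))
  tab <- data.frame(
    id = rows$id, class = rows$activity_class,
    delta_e = ifelse(is.na(rows$delta_e), "",
                     sprintf("%.1f", rows$delta_e)),
    fit_rmsd = ifelse(is.na(rows$fit_rmsd), "",
                      sprintf("%.2f", rows$fit_rmsd)),
    c_h = sprintf("%d/%d", rows$n_conf, rows$n_hit),
    stringsAsFactors = FALSE
  )
  for (a in anchors)
    tab[[a]] <- vapply(rows$id, function(id)
      hb_cell(report$hbonds[[id]], a), character(1))
  tab
}

#' Render a screen report
#'
#' @param report a `screen_report` from [screen()].
#' @param format one of `tsv`, `csv`, `markdown`, `json`. The JSON format
#'   round-trips losslessly through [read_report_json()]; the tabular
#'   formats mirror the classical screening-table column order (strain,
#'   fit RMSD, conformers/hits, per-anchor d(angle) with `**` flags on
#'   borderline cells).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, format = c("tsv", "csv", "markdown",
                                             "json"), path) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      schema = "dopaphore/screen_report/1",
      rows = report$rows,
      summary = report$summary,
      hbonds = report$hbonds
    )
    writeLines(jsonlite::toJSON(payload, dataframe = "columns",
                                auto_unbox = TRUE, digits = NA,
                                na = "null"), path)
    return(invisible(path))
  }
  tab <- report_table(report)
  if (format == "markdown") {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  } else {
    utils::write.table(tab, path, sep = if (format == "tsv") "\t" else ",",
                       row.names = FALSE, quote = format == "csv")
  }
  invisible(path)
}

#' Read a JSON screen report back
#' @param path file written by [render_report()] with `format = "json"`.
#' @return a `screen_report` (without the non-serialized pose objects).
#' @export
read_report_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rows <- as.data.frame(p$rows, stringsAsFactors = FALSE)
  summary <- as.data.frame(p$summary, stringsAsFactors = FALSE)
  hbonds <- lapply(p$hbonds, function(h)
    as.data.frame(h, stringsAsFactors = FALSE))
  structure(list(rows = rows, summary = summary, best_hits = list(),
                 hbonds = hbonds, model = NULL),
            class = "screen_report")
}

#' Run the ablation suite
#'
#' Screens the library against (1) the full refined model, (2) the model
#' without excluded volumes (Ser-TM5 optional), and (3) the model without
#' excluded volumes with Ser-TM5 promoted to essential, and verifies the
#' expected monotonicity relations between the hit sets (removing
#' constraints can only add hits; adding the essential requirement can
#' only remove them).
#'
#' @param model the calibrated [pharm_model()].
#' @param ensembles conformer ensembles of the library.
#' @param anchor_set optional [anchor_set()] for hydrogen-bond columns.
#' @return list with `refined`, `no_ev`, `no_ev_tm5ess` screen reports
#'   and `monotone` (logical: both subset relations hold).
#' @export
run_ablation_suite <- function(model, ensembles, anchor_set = NULL) {
  m_noev <- ablate(model, "drop_excluded_volumes")
  m_ess <- ablate(m_noev, "tm5_essential")
  r0 <- screen(ensembles, model, anchor_set)
  r1 <- screen(ensembles, m_noev, anchor_set)
  r2 <- screen(ensembles, m_ess, anchor_set)
  hitset <- function(r) r$rows$id[r$rows$n_hit > 0]
  monotone <- all(hitset(r0) %in% hitset(r1)) &&
    all(hitset(r2) %in% hitset(r1))
  list(refined = r0, no_ev = r1, no_ev_tm5ess = r2, monotone = monotone)
}
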