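# Evaluation harness: per-target statistics on the normalized brightness
# map, comparison against each case's predicted relation, the full battery
# driver with CSV/JSON reports and figure-style panel export, and the row
# profile used for the display convention (one row of normalized activity).

#' Evaluate one illusion case against the model output
#'
#' For mean-difference cases the statistic is `mean(brightness[A]) -
#' mean(brightness[B])` over the eroded target masks. For the
#' contrast-contrast case it is the difference of the RMS brightness
#' contrast (standard deviation around the mask mean) within the two
#' central-patch masks. The observed relation is derived from the sign and
#' magnitude of the statistic: differences beyond `delta` count as a
#' direction, absolute differences below `delta_eq` count as equality.
#'
#' @param case An [illusion_case][generate_stimulus()].
#' @param outputs A `model_outputs` from [run_model()] on `case$image`.
#' @param delta Direction tolerance on the normalized brightness scale.
#' @param delta_eq Equality tolerance.
#' @return An `illusion_result`: list with per-target statistics, the
#'   difference, predicted and observed relations, and `pass`.
#' @export
evaluate_case <- function(case, outputs, delta = 0.01, delta_eq = 0.005) {
  stopifnot(inherits(case, "illusion_case"),
            inherits(outputs, "model_outputs"))
  b <- outputs$brightness$values
  mA <- case$target_masks$A; mB <- case$target_masks$B
  if (sum(mA) == 0 || sum(mB) == 0) stop("empty target mask")
  if (!identical(dim(b), dim(mA))) stop("mask does not match the output")
  if (case$statistic == "mean_difference") {
    stat_a <- mean(b[mA]); stat_b <- mean(b[mB])
  } else {
    stat_a <- stats::sd(b[mA]); stat_b <- stats::sd(b[mB])
  }
  diff <- stat_a - stat_b
  observed <- if (case$statistic == "rms_contrast_difference") {
    if (diff < -delta) "A_lower_contrast_than_B" else "A_equals_B"
  } else if (diff > delta) {
    "A_brighter_than_B"
  } else if (diff < -delta) {
    "B_brighter_than_A"
  } else if (abs(diff) < delta_eq) {
    "A_equals_B"
  } else {
    "indeterminate"
  }
  structure(list(name = case$name, stat_a = stat_a, stat_b = stat_b,
                 difference = diff, statistic = case$statistic,
                 relation_predicted = case$relation,
                 relation_observed = observed,
                 pass = identical(observed, case$relation),
                 iterations = c(on = outputs$on_fill$iterations,
                                off = outputs$off_fill$iterations)),
            class = "illusion_result")
}

#' @export
print.illusion_result <- function(x, ...) {
  cat(sprintf("<%s: diff %+0.4f, predicted %s, observed %s -> %s>\n",
              x$name, x$difference, x$relation_predicted,
              x$relation_observed, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Extract one row of the normalized brightness map
#'
#' @param brightness A `brightness_map` (or numeric matrix).
#' @param row Row index.
#' @return Data frame with `col` and `value`, ordered by column.
#' @export
extract_row_profile <- function(brightness, row) {
  v <- if (inherits(brightness, "brightness_map")) brightness$values
       else as.matrix(brightness)
  if (row < 1 || row > nrow(v)) stop("row out of range")
  data.frame(col = seq_len(ncol(v)), value = v[row, ])
}

#' Run the illusion battery
#'
#' Generates each requested stimulus, runs the full model, evaluates the
#' predicted relation, and (optionally) writes a machine-readable report
#' plus per-case panels. A failing stage aborts only that case, which is
#' recorded as an error row.
#'
#' @param names Subset of registry names; default all 16.
#' @param config A [model_config()] applied to every case (default: scaled
#'   per case to its grid size).
#' @param size Grid size passed to the generators.
#' @param delta,delta_eq Tolerances of [evaluate_case()].
#' @param out_dir If non-`NULL`, report CSV + JSON summary and per-case
#'   panel images/profiles are written there.
#' @param verbose Log progress to stderr.
#' @return A list with `report` (one data-frame row per case), `results`
#'   (the `illusion_result`s) and `outputs` (per-case `model_outputs`).
#' @export
run_battery <- function(names = NULL, config = NULL, size = 128,
                        delta = 0.01, delta_eq = 0.005, out_dir = NULL,
                        verbose = FALSE) {
  if (is.null(names)) names <- STIMULUS_NAMES
  unknown <- setdiff(names, STIMULUS_NAMES)
  if (length(unknown)) stop("unknown stimuli: ", paste(unknown, collapse = ", "))
  results <- list(); outputs <- list()
  rows <- lapply(names, function(nm) {
    tryCatch({
      case <- generate_stimulus(nm, list(size = size))
      cfg <- if (is.null(config)) model_config(size = size) else config
      out <- run_model(case$image, cfg, verbose = verbose)
      res <- evaluate_case(case, out, delta = delta, delta_eq = delta_eq)
      results[[nm]] <<- res
      outputs[[nm]] <<- out
      if (!is.null(out_dir)) export_case_panels(case, out, out_dir)
      if (verbose) message(sprintf("[battery] %-22s diff %+0.4f %s", nm,
                                   res$difference,
                                   if (res$pass) "PASS" else "FAIL"))
      data.frame(name = nm, statistic = res$statistic,
                 stat_a = res$stat_a, stat_b = res$stat_b,
                 difference = res$difference,
                 relation_predicted = res$relation_predicted,
                 relation_observed = res$relation_observed,
                 pass = res$pass, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(name = nm, statistic = NA_character_, stat_a = NA_real_,
                 stat_b = NA_real_, difference = NA_real_,
                 relation_predicted = NA_character_,
                 relation_observed = NA_character_, pass = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "battery_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_cases = nrow(report), n_pass = sum(report$pass),
           cases = report),
      file.path(out_dir, "battery_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(report = report, results = results, outputs = outputs)
}

# write the figure-style panels for one case: input, pathway maps, oriented
# boundary maps and masks, fill layers, brightness, and the row profile
export_case_panels <- function(case, outputs, out_dir) {
  d <- file.path(out_dir, case$name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  grids <- list(input = as_matrix(case$image),
                contrast_on = outputs$contrast$on,
                contrast_off = outputs$contrast$off,
                luminance_on = outputs$luminance$on,
                luminance_off = outputs$luminance$off,
                lbd_h = outputs$lbd$H, lbd_v = outputs$lbd$V,
                gbd_h = outputs$gbd$H, gbd_v = outputs$gbd$V,
                mask_h = outputs$mask$H * 1, mask_v = outputs$mask$V * 1,
                fill_on = outputs$on_fill$activity,
                fill_off = outputs$off_fill$activity,
                brightness = outputs$brightness$values)
  for (nm in names(grids)) {
    write_grid_csv(grids[[nm]], file.path(d, paste0(nm, ".csv")))
    write_grid_png(grids[[nm]], file.path(d, paste0(nm, ".png")))
  }
  prof <- extract_row_profile(outputs$brightness, case$params$row)
  utils::write.csv(prof, file.path(d, "row_profile.csv"), row.names = FALSE)
  invisible(d)
}

#' Command-line entry point
#'
#' Drives the package from the shell; see `inst/cli/contourfill.R`.
#' Subcommands: `stimulus --name NAME [--size N] --out DIR` writes a
#' stimulus and its masks; `run --stimulus NAME [--size N] [--row R] --out
#' DIR` runs the model on one case and writes all panels; `battery
#' [--only a,b,c] [--size N] --out DIR` runs the directional battery and
#' writes the report.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the exit status (0 on success).
#' @export
contourfill_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: contourfill <stimulus|run|battery> [options]",
    "  stimulus --name NAME [--size N] --out DIR",
    "  run      --stimulus NAME [--size N] [--row R] --out DIR",
    "  battery  [--only a,b,c] [--size N] --out DIR", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  size <- as.integer(opt("--size", "128"))
  out <- opt("--out", "contourfill_out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (cmd == "stimulus") {
    nm <- opt("--name")
    if (is.null(nm)) stop(usage)
    case <- generate_stimulus(nm, list(size = size))
    write_grid_csv(case$image, file.path(out, paste0(nm, ".csv")))
    write_grid_png(case$image, file.path(out, paste0(nm, ".png")),
                   rescale = FALSE)
    for (t in names(case$target_masks)) {
      write_grid_csv(case$target_masks[[t]] * 1,
                     file.path(out, paste0(nm, "_mask_", t, ".csv")))
      write_grid_png(case$target_masks[[t]] * 1,
                     file.path(out, paste0(nm, "_mask_", t, ".png")))
    }
    message("wrote stimulus '", nm, "' to ", out)
  } else if (cmd == "run") {
    nm <- opt("--stimulus")
    if (is.null(nm)) stop(usage)
    case <- generate_stimulus(nm, list(size = size))
    row <- as.integer(opt("--row", as.character(case$params$row)))
    case$params$row <- row
    outputs <- run_model(case$image, model_config(size = size),
                         verbose = TRUE)
    export_case_panels(case, outputs, out)
    res <- evaluate_case(case, outputs)
    print(res)
  } else if (cmd == "battery") {
    only <- opt("--only")
    names <- if (is.null(only)) NULL else strsplit(only, ",")[[1]]
    bat <- run_battery(names = names, size = size, out_dir = out,
                       verbose = TRUE)
    print(bat$report[, c("name", "difference", "relation_observed", "pass")])
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
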