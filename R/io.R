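# File formats: CSV for measurements and profiles (comma-separated,
# '.' decimal, '#'-prefixed metadata header lines), JSON for plans,
# machine files, configuration and reports. Lengths are in cm except gap
# widths, which follow the measurement convention in mm.

#' Write or read a measurement set CSV
#'
#' @param ms a `measurement_set` data frame.
#' @param path file path.
#' @return `read_measurements_csv()` returns the measurement set.
#' @export
write_measurements_csv <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(ms, "seed")
  writeLines(sprintf("# dualmlc-measurements-v1 units=cm,gap=mm seed=%s",
                     if (is.null(seed)) NA else seed), con)
  utils::write.csv(as.data.frame(ms), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# dualmlc-measurements-v1", hdr))
    stop("not a dualmlc measurements file: ", path)
  df <- utils::read.csv(path, skip = 1)
  class(df) <- c("measurement_set", class(df))
  seed <- suppressWarnings(as.integer(sub(".*seed=([-0-9NA]+).*", "\\1",
                                          hdr)))
  attr(df, "seed") <- seed
  df
}

# key=value metadata on '#' header lines
.meta_line <- function(tag, meta) {
  if (!length(meta)) return(paste0("# ", tag))
  kv <- vapply(names(meta), function(k)
    sprintf("%s=%s", k, format(meta[[k]], digits = 12)), character(1))
  paste0("# ", tag, " ", paste(kv, collapse = " "))
}

.parse_meta <- function(line) {
  kv <- regmatches(line,
                   gregexpr("[A-Za-z_]+=[^ ]+", line))[[1]]
  keys <- sub("=.*", "", kv)
  vals <- sub("^[^=]+=", "", kv)
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  stats::setNames(out, keys)
}

#' Run configuration
#'
#' Validated configuration object for the simulation and commissioning
#' pipeline; unknown keys are rejected. All lengths in cm, gaps in mm.
#'
#' @param ... configuration values; see `names(run_config())` for the
#'   full set.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    noise_sd = 0.005,
    grid_spacing = 0.1,
    true_offset = 0.007,
    true_gain = 0,
    true_curvature = 0,
    true_tip_width = 0,
    true_tng_width = 0.05,
    true_transmission = 0.0047,
    gaps_mm = c(2, 4, 6, 10, 14, 16, 20),
    sweep_positions = c(0, -3, 3, 5, 10, 12, 13),
    junctions = c(0, -10, 10),
    edge_centers = c(-13, -10, -5, -3, 0, 3, 5, 10, 12, 13),
    n_plans = 2,
    techniques = c("vmat", "sw_vmat", "dmlc"),
    modulation = 6,
    tng_widths = seq(0, 0.1, by = 0.01),
    rms_offsets = seq(-0.03, 0.03, by = 0.01),
    scan_half_range = 0.02,
    scan_step = 0.01,
    alpha = 0.05,
    curvature_k = 3,
    criteria = c("3G2", "2L2"),
    threshold = 10
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, extra)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path file path.
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

# stable small hash of an object's numeric content (for manifests)
.small_hash <- function(x) {
  s <- paste(format(unlist(x), digits = 12), collapse = "|")
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 1000000007
  sprintf("%09d", h)
}

#' Generate the full virtual measurement bundle
#'
#' Runs every virtual session the commissioning pipeline consumes:
#' sweeping gaps, complementary bars for both layers, static strip
#' edges, abutting fields, and one modulated plan suite per technique.
#'
#' @param gt a [ground_truth()].
#' @param cfg a [run_config()].
#' @return A list (class `session_bundle`) with elements `sweep`,
#'   `bars`, `edges`, `abutting`, `suites`.
#' @export
gen_bundle <- function(gt, cfg = run_config()) {
  bundle <- list(
    sweep = gen_sweep_session(gt, cfg$gaps_mm, cfg$sweep_positions),
    bars = list(gen_bar_session(gt, "proximal"),
                gen_bar_session(gt, "distal")),
    edges = gen_edge_session(gt, cfg$edge_centers),
    abutting = gen_abutting_session(gt, cfg$junctions),
    suites = lapply(cfg$techniques, function(tech)
      gen_plan_suite(gt, cfg$n_plans, tech, cfg$modulation,
                     spacing = cfg$grid_spacing)))
  structure(bundle, class = "session_bundle")
}

#' Write or read a session bundle directory
#'
#' Serializes a bundle to plain-text artifacts: measurement CSVs,
#' profile CSVs, plan JSONs, plus a `manifest.json` recording the seed,
#' a hash of the hidden ground truth (not its values) and the session
#' inventory.
#'
#' @param bundle a `session_bundle` from [gen_bundle()].
#' @param dir output directory (created if needed).
#' @param gt optional [ground_truth()] whose seed/hash go into the
#'   manifest.
#' @return `read_bundle()` returns the bundle.
#' @export
write_bundle <- function(bundle, dir, gt = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "plans"), showWarnings = FALSE)
  dir.create(file.path(dir, "arrays"), showWarnings = FALSE)
  write_measurements_csv(bundle$sweep, file.path(dir, "sweep.csv"))
  for (b in bundle$bars)
    for (nm in c("pattern_a", "pattern_b", "sum")) {
      p <- b[[nm]]
      p$meta$layer <- b$layer
      write_profile_csv(p, file.path(dir,
                                     sprintf("bars_%s_%s.csv", b$layer, nm)))
    }
  for (i in seq_along(bundle$edges)) {
    e <- bundle$edges[[i]]
    p <- e$profile
    p$meta$x_nom <- e$x_nom
    p$meta$width <- e$width
    write_profile_csv(p, file.path(dir, sprintf("edges_%02d.csv", i)))
  }
  for (i in seq_along(bundle$abutting)) {
    a <- bundle$abutting[[i]]
    for (nm in c("field_a", "field_b", "sum")) {
      p <- a[[nm]]
      p$meta$junction <- a$junction
      write_profile_csv(p, file.path(dir,
                                     sprintf("abutting_%02d_%s.csv", i, nm)))
    }
  }
  chambers <- list()
  suite_meta <- list()
  for (s in bundle$suites) {
    for (pl in s$plans)
      write_plan_json(pl, file.path(dir, "plans",
                                    paste0(pl$label, ".json")))
    for (a in s$arrays) {
      lbl <- a$plan[1]
      con <- file(file.path(dir, "arrays", paste0(lbl, ".csv")), "w")
      writeLines("# dualmlc-array-v1 radius=10.5 units=cm", con)
      utils::write.csv(a, con, row.names = FALSE)
      close(con)
    }
    chambers[[length(chambers) + 1]] <- s$chambers
    suite_meta[[length(suite_meta) + 1]] <-
      list(technique = s$technique, modulation = s$modulation,
           plans = vapply(s$plans, function(p) p$label, character(1)))
  }
  ch <- do.call(rbind, chambers)
  con <- file(file.path(dir, "chambers.csv"), "w")
  writeLines("# dualmlc-chambers-v1 units=cm", con)
  utils::write.csv(ch, con, row.names = FALSE)
  close(con)
  manifest <- list(
    format = "dualmlc-bundle-v1",
    seed = if (is.null(gt)) NA else gt$seed,
    noise_sd = if (is.null(gt)) NA else gt$noise_sd,
    ground_truth_hash = if (is.null(gt)) NA else
      .small_hash(gt$true_params),
    suites = suite_meta,
    inventory = sort(list.files(dir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(manifest$format) || manifest$format != "dualmlc-bundle-v1")
    stop("not a dualmlc bundle directory: ", dir)
  sweep <- read_measurements_csv(file.path(dir, "sweep.csv"))
  bars <- lapply(c("proximal", "distal"), function(lay) {
    ps <- lapply(c("pattern_a", "pattern_b", "sum"), function(nm)
      read_profile_csv(file.path(dir, sprintf("bars_%s_%s.csv", lay, nm))))
    structure(list(layer = lay, pattern_a = ps[[1]], pattern_b = ps[[2]],
                   sum = ps[[3]]), class = "bar_session")
  })
  edge_files <- sort(list.files(dir, "^edges_", full.names = TRUE))
  edges <- structure(lapply(edge_files, function(f) {
    p <- read_profile_csv(f)
    list(x_nom = p$meta$x_nom, width = p$meta$width, profile = p)
  }), class = "edge_session")
  ab_sum <- sort(list.files(dir, "^abutting_[0-9]+_sum", full.names = TRUE))
  abutting <- structure(lapply(ab_sum, function(f) {
    p <- read_profile_csv(f)
    fa <- read_profile_csv(sub("_sum", "_field_a", f))
    fb <- read_profile_csv(sub("_sum", "_field_b", f))
    list(junction = p$meta$junction, field_a = fa, field_b = fb, sum = p)
  }), class = "abutting_session")
  chambers <- utils::read.csv(file.path(dir, "chambers.csv"), skip = 1)
  suites <- lapply(seq_len(NROW(manifest$suites)), function(i) {
    sm <- if (is.data.frame(manifest$suites)) manifest$suites[i, ]
      else manifest$suites[[i]]
    labels <- unlist(sm$plans)
    plans <- lapply(labels, function(l)
      read_plan_json(file.path(dir, "plans", paste0(l, ".json"))))
    arrays <- lapply(labels, function(l) {
      f <- file.path(dir, "arrays", paste0(l, ".csv"))
      if (file.exists(f)) utils::read.csv(f, skip = 1) else NULL
    })
    structure(list(plans = plans,
                   chambers = chambers[chambers$plan %in% labels, ],
                   arrays = arrays,
                   technique = if (is.list(sm$technique))
                     sm$technique[[1]] else sm$technique,
                   modulation = if (is.list(sm$modulation))
                     sm$modulation[[1]] else sm$modulation),
              class = "plan_suite")
  })
  structure(list(sweep = sweep, bars = bars, edges = edges,
                 abutting = abutting, suites = suites,
                 manifest = manifest),
            class = "session_bundle")
}

#' Write a commissioning report as JSON
#'
#' @param report a `commissioning_report` from [run_commissioning()].
#' @param path file path.
#' @return `read_report_json()` returns the parsed report list.
#' @export
write_report_json <- function(report, path) {
  flatten_fit <- function(f) {
    if (inherits(f, "fit_result"))
      list(parameter = f$parameter, estimate = f$estimate, se = f$se,
           decision = f$decision, rule = f$rule,
           diagnostics = f$diagnostics, details = f$details)
    else lapply(f, flatten_fit)
  }
  obj <- list(
    format = "dualmlc-report-v1",
    package_version = as.character(utils::packageVersion("dualmlc")),
    parameters = list(
      offset = report$params$offset, gain = report$params$gain,
      curvature = report$params$curvature,
      tip_width = report$params$tip_width,
      layer_transmission = as.list(report$params$layer_transmission),
      tng_width = report$params$tng_width,
      dynamic_min_gap = report$params$dynamic_min_gap),
    decisions = report$decisions,
    fits = lapply(report$fits, flatten_fit),
    config = report$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dualmlc-report-v1")
    stop("not a dualmlc report file: ", path)
  obj
}
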