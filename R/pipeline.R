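# Configuration-driven orchestration: ingest -> per-subject inversion ->
# group PEB/BMR/BMA -> cross-validation -> report tables.

#' Read a multichannel recording
#'
#' Supports plain CSV (one column per channel, header row of labels) and a
#' minimal continuous European Data Format (EDF) reader (identical sampling
#' rate across channels).
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @param sfreq sampling rate in Hz (required for CSV; read from the header
#'   for EDF).
#' @param reref apply a common-average re-reference (subtract the channel
#'   mean at every sample).
#' @return A `recording`.
#' @export
read_timeseries <- function(path, format = NULL, sfreq = NULL, reref = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  if (!format %in% c("csv", "edf")) stop("unknown format: ", format)
  if (format == "csv") {
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1L) {
      stop("inconsistent channel lengths in ", path,
           " (rows have differing field counts)")
    }
    df <- utils::read.csv(path, check.names = FALSE)
    X <- t(as.matrix(df))
    if (!is.numeric(X)) stop("non-numeric values in ", path)
    if (is.null(sfreq)) stop("sfreq is required for CSV recordings")
    rec <- recording(X, sfreq, labels = colnames(df))
  } else {
    rec <- read_edf(path)
  }
  if (reref) rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# minimal EDF reader: continuous recordings, equal sampling rate per channel
read_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (nchar(x, type = "bytes") < n) {
      stop("EDF file truncated at byte offset ", seek(con), " in ", path)
    }
    trimws(x)
  }
  rd(8)                        # version
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  rd(8)                        # header bytes
  rd(44)                       # reserved
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF header corrupt in ", path)
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports one sampling rate across channels only")
  }
  header_bytes <- 256L + 256L * ns
  need <- header_bytes + 2 * sum(spr) * n_rec
  if (sz < need) {
    stop("EDF file truncated at byte offset ", sz, " (expected ", need,
         " bytes) in ", path)
  }
  X <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      phys <- pmin_[s] + (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) /
        (dmax_[s] - dmin_[s])
      X[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  recording(X, spr[1] / dur, labels = labels)
}

# minimal EDF writer used to build fixtures in tests; inverse of read_edf
write_edf <- function(rec, path, record_len = 1) {
  ns <- nrow(rec$data)
  spr <- round(rec$sfreq * record_len)
  n_rec <- floor(ncol(rec$data) / spr)
  pmax_ <- max(abs(rec$data), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeChar(substr(s, 1, w), con, eos = NULL)
  }
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256L + 256L * ns, 8); pad("", 44)
  pad(n_rec, 8); pad(format(record_len), 8); pad(ns, 4)
  for (l in rec$labels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(format(-pmax_, digits = 6), 8)
  for (i in seq_len(ns)) pad(format(pmax_, digits = 6), 8)
  for (i in seq_len(ns)) pad(-32768L, 8)
  for (i in seq_len(ns)) pad(32767L, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- rec$data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round(-32768 + (seg + pmax_) * 65535 / (2 * pmax_)))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Analysis run configuration
#'
#' @param input either a `cohort_config` (synthetic input) or a path to a
#'   cohort directory written by [write_cohort()].
#' @param seed master seed for synthetic generation.
#' @param contrasts list of label pairs to contrast at the group level;
#'   within each pair the second label is the group coded +1.
#' @param subsets named subsets evaluated by LOSOCV (labels into the network
#'   spec's subsets).
#' @param state_plan list with `train` (label pair) and `test` (label) for
#'   leave-one-state-out generalization, or NULL to skip.
#' @param fit_options list with `max_iter` and `tol` for [fit_vl()].
#' @param constants_file optional path to a constants YAML.
#' @param out_dir where [run_pipeline()] leaves nothing unless
#'   [write_report()] is called; recorded in the manifest.
#' @return A validated `run_config`.
#' @export
run_config <- function(input = cohort_config(), seed = 1L,
                       contrasts = list(c("control", "uws"),
                                        c("mcs", "uws"),
                                        c("control", "mcs")),
                       subsets = c("full", "frontoparietal", "parietal"),
                       state_plan = list(train = c("control", "uws"),
                                         test = "holdout"),
                       fit_options = list(max_iter = 24L, tol = 1e-2),
                       constants_file = NULL,
                       out_dir = NULL) {
  if (!inherits(input, "cohort_config")) {
    if (!is.character(input) || !dir.exists(input)) {
      stop("input must be a cohort_config or an existing cohort directory")
    }
  }
  if (!is.null(constants_file) && !file.exists(constants_file)) {
    stop("constants file not found: ", constants_file)
  }
  structure(list(input = input, seed = seed, contrasts = contrasts,
                 subsets = subsets, state_plan = state_plan,
                 fit_options = fit_options, constants_file = constants_file,
                 out_dir = out_dir),
            class = "run_config")
}

# FNV-1a hash of a serialized object, as hex
config_hash <- function(x) {
  h <- fnv1a32(serialize(x, NULL, version = 2))
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full analysis pipeline
#'
#' Executes: ingest/simulate, per-subject variational-Laplace inversion,
#' group PEB with exhaustive model reduction and Bayesian model averaging for
#' each contrast, leave-one-subject-out cross-validation over hypothesis- and
#' data-driven connection subsets, and leave-one-state-out generalization to
#' the holdout group. Stage failures yield a partial report with diagnostics;
#' downstream stages are skipped.
#'
#' @param config a `run_config`.
#' @param quiet suppress per-stage messages.
#' @return A `run_report`: per-stage outputs, timings, config hash and seeds.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  constants <- if (is.null(config$constants_file)) load_constants() else
    load_constants(config$constants_file)
  spec <- default_dmn()
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 version = as.character(utils::packageVersion("specdcm")),
                 timings = list(), failed = NULL)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, fun) {
    if (!is.null(report$failed)) return(NULL)
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e) {
      report$failed <<- list(stage = name, error = conditionMessage(e))
      say("stage ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
    report$timings[[name]] <<- round(proc.time()[3] - t0, 2)
    out
  }
  cohort <- stage("ingest", function() {
    if (inherits(config$input, "cohort_config")) {
      say("simulating synthetic cohort (seed ", config$seed, ")")
      make_cohort(config$input, seed = config$seed, spec = spec,
                  constants = constants)
    } else {
      say("loading cohort from ", config$input)
      read_cohort(config$input)
    }
  })
  posteriors <- stage("fit", function() {
    say("inverting ", length(cohort$subjects), " subjects")
    priors <- default_priors(constants)
    lapply(cohort$subjects, function(s) {
      fit_vl(s$csd, priors, spec, cohort$lead, constants,
             max_iter = config$fit_options$max_iter,
             tol = config$fit_options$tol)
    })
  })
  report$fit_summary <- if (!is.null(posteriors)) {
    data.frame(id = vapply(cohort$subjects, `[[`, "", "id"),
               label = cohort$labels,
               free_energy = vapply(posteriors, `[[`, 0, "free_energy"),
               iterations = vapply(posteriors,
                                   function(p) length(p$trace) - 1L,
                                   integer(1)))
  }
  labels <- cohort$labels
  peb_out <- stage("peb", function() {
    lapply(config$contrasts, function(ct) {
      say("contrast ", ct[1], " vs ", ct[2])
      sel <- which(labels %in% ct)
      X <- design_matrix(factor(labels[sel], levels = ct))
      peb <- fit_peb(posteriors[sel], X)
      space <- model_search(peb, "exhaustive")
      avg <- bma(space)
      thr <- threshold_bma(avg)
      list(contrast = ct, peb = peb, bma = avg, threshold = thr,
           ranking = rank_connections(avg))
    })
  })
  if (!is.null(peb_out)) {
    report$bma_tables <- lapply(peb_out, function(p) {
      tab <- p$bma$effects
      tab$contrast <- paste(p$contrast, collapse = "_vs_")
      tab$retained <- tab$pp > 0.99
      tab
    })
  }
  cv_out <- stage("crossval", function() {
    lapply(seq_along(config$contrasts), function(ci) {
      ct <- config$contrasts[[ci]]
      sel <- which(labels %in% ct)
      lab <- factor(labels[sel], levels = ct)
      subs <- lapply(config$subsets, function(nm) spec$subsets[[nm]])
      names(subs) <- config$subsets
      cvs <- lapply(subs, function(sub) {
        losocv(posteriors[sel], lab, subset = sub, positive = ct[1],
               ids = vapply(cohort$subjects[sel], `[[`, "", "id"))
      })
      step <- stepwise_subset(posteriors[sel], lab,
                              ranking = peb_out[[ci]]$ranking,
                              positive = ct[1])
      list(contrast = ct, cv = cvs, stepwise = step)
    })
  })
  if (!is.null(cv_out)) {
    report$cv_tables <- do.call(rbind, lapply(cv_out, function(co) {
      do.call(rbind, lapply(names(co$cv), function(nm) {
        tab <- co$cv[[nm]]$table
        tab$subset <- nm
        tab$contrast <- paste(co$contrast, collapse = "_vs_")
        tab$balanced_accuracy <- co$cv[[nm]]$balanced_accuracy
        tab
      }))
    }))
    report$stepwise_tables <- lapply(cv_out, function(co) {
      st <- co$stepwise$steps
      st$contrast <- paste(co$contrast, collapse = "_vs_")
      st
    })
  }
  state_out <- stage("state", function() {
    sp <- config$state_plan
    if (is.null(sp)) return(NULL)
    sel <- which(labels %in% sp$train)
    tst <- which(labels == sp$test)
    best_edge <- peb_out[[1]]$ranking[1]
    subs <- list(frontoparietal = spec$subsets$frontoparietal,
                 best_single = best_edge)
    lapply(subs, function(sub) {
      leave_one_state_out(posteriors[sel],
                          factor(labels[sel], levels = sp$train),
                          posteriors[tst], subset = sub,
                          ids = vapply(cohort$subjects[tst], `[[`, "", "id"))
    })
  })
  if (!is.null(state_out)) {
    report$state_tables <- do.call(rbind, lapply(names(state_out), function(nm) {
      tab <- state_out[[nm]]$table
      tab$subset <- nm
      tab
    }))
  }
  report$cohort_labels <- labels
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config ", x$config_hash, ", seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$failed)) {
    cat("FAILED at stage", x$failed$stage, ":", x$failed$error, "\n")
  }
  for (nm in names(x$timings)) cat(sprintf("  %-8s %6.1f s\n", nm, x$timings[[nm]]))
  invisible(x)
}

#' Write a run report to disk
#'
#' CSV tables (BMA effects, cross-validation probabilities, stepwise steps,
#' state-generalization probabilities, per-subject fit summaries) plus a JSON
#' manifest with the config hash and seed. Reading the tables back reproduces
#' the in-memory values.
#'
#' @param report a `run_report`.
#' @param path output directory.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(path, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(report$fit_summary)) wr(report$fit_summary, "fit_summary.csv")
  if (!is.null(report$bma_tables)) {
    wr(do.call(rbind, report$bma_tables), "bma_effects.csv")
  }
  if (!is.null(report$cv_tables)) wr(report$cv_tables, "losocv_pp.csv")
  if (!is.null(report$stepwise_tables)) {
    wr(do.call(rbind, report$stepwise_tables), "stepwise.csv")
  }
  if (!is.null(report$state_tables)) wr(report$state_tables, "state_pp.csv")
  manifest <- list(config_hash = report$config_hash, seed = report$seed,
                   version = report$version, timings = report$timings,
                   failed = report$failed, files = basename(files))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, file.path(path, "manifest.json")))
}
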