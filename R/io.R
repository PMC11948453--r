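# Formats and configuration: trace binary + JSON sidecar, event CSV tables,
# run configuration with schema validation.

trace_sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an ion trace as flat binary with a JSON sidecar header
#'
#' Samples are stored as little-endian 32-bit floats (nA); acquisition
#' metadata goes to a `.json` sidecar next to the binary file.
#'
#' @param trace An [ion_trace()].
#' @param path Output path for the binary payload (conventionally `.bin`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ion_trace"))
  header <- list(format = "mitopore-trace", version = 1L,
                 sampling_rate_hz = trace$sampling_rate_hz,
                 voltage_mV = trace$voltage_mV,
                 units = "nA",
                 n_samples = length(trace$samples),
                 dtype = "float32_le",
                 meta = trace$meta)
  jsonlite::write_json(header, trace_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an ion trace written by [write_trace()]
#'
#' Validates the sidecar header (format, units, sampling rate) and checks the
#' payload length against the declared sample count.
#'
#' @param path Path to the binary payload.
#' @return An [ion_trace()].
#' @export
read_trace <- function(path) {
  sc <- trace_sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar header: ", sc, call. = FALSE)
  if (!file.exists(path)) stop("missing trace payload: ", path, call. = FALSE)
  h <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(h$format, "mitopore-trace"))
    stop("not a mitopore trace header", call. = FALSE)
  if (is.null(h$sampling_rate_hz) || h$sampling_rate_hz <= 0)
    stop("invalid sampling_rate_hz in header", call. = FALSE)
  if (!identical(h$units, "nA"))
    stop("unit mismatch: expected nA, got ", h$units, call. = FALSE)
  n <- as.integer(h$n_samples)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(x) != n)
    stop("truncated payload: expected ", n, " samples, read ", length(x),
         call. = FALSE)
  ion_trace(x, h$sampling_rate_hz, h$voltage_mV %||% NA_real_,
            meta = as.list(h$meta %||% list()))
}

#' Write an event table as CSV
#'
#' Event tables are the interchange surface between pipeline stages; indices
#' are 0-based half-open, as stated in the header comment line.
#'
#' @param events Event `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mitopore events v1; start_idx/end_idx are 0-based half-open sample indices",
             con)
  utils::write.table(events, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read an event table written by [write_events_csv()]
#' @param path CSV path.
#' @return Event `data.frame`.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("missing event table: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Allowed run-configuration schema: section -> known keys.
config_schema <- list(
  seed = NULL,
  trace = c("duration_s", "event_rate_hz", "open_pore_current_nA",
            "baseline_noise_sd_nA", "sampling_rate_hz", "voltage_mV"),
  mixture = c("fragment", "mtDNA", "syDNA", "pcDNA"),
  detect = c("window_s", "k_sigma", "k_close", "min_dur_us", "max_dur_us",
             "edge_frac"),
  classify = c("kernel_scale", "cost", "n_folds", "train_n_per_class"),
  quantify = c("positive_class", "kappa", "mt_length_bp", "genome_size_bp"),
  schema_version = NULL
)

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON. Unknown sections or keys are rejected so that typos
#' fail loudly; missing values fall back to package defaults.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return Validated config list of class `"run_config"` with attribute
#'   `config_hash` (MD5 of the file).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    keys <- config_schema[[sec]]
    if (!is.null(keys) && is.list(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), keys)
      if (length(bad))
        stop("unknown key(s) in config section '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Default pipeline configuration
#'
#' A small two-class (gDNA fragments vs mtDNA) simulate-detect-classify-count
#' workflow; the ~10:1 fragment:mtDNA mixture mirrors the steady-state
#' counting background the enzymatic assay produces.
#'
#' @param seed Integer seed.
#' @return `"run_config"` list (no file hash).
#' @export
default_run_config <- function(seed = 1) {
  cfg <- list(
    seed = seed,
    trace = list(duration_s = 2, event_rate_hz = 150,
                 open_pore_current_nA = 10, baseline_noise_sd_nA = 0.03,
                 sampling_rate_hz = 5e5, voltage_mV = 150),
    mixture = list(fragment = 10 / 11, mtDNA = 1 / 11),
    detect = list(window_s = 0.1, k_sigma = 6, k_close = 1, min_dur_us = 20,
                  max_dur_us = 1e5, edge_frac = 0.1),
    classify = list(kernel_scale = 2, cost = 1, n_folds = 5,
                    train_n_per_class = 500),
    quantify = list(positive_class = "mtDNA", kappa = 1,
                    mt_length_bp = 16569, genome_size_bp = 6e9),
    schema_version = "1"
  )
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

merge_config <- function(cfg) {
  def <- default_run_config(cfg$seed %||% 1)
  for (sec in names(def)) {
    if (is.list(def[[sec]])) {
      for (k in names(def[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- def[[sec]][[k]]
    } else if (is.null(cfg[[sec]])) cfg[[sec]] <- def[[sec]]
  }
  cfg
}

#' Run the end-to-end quantification pipeline
#'
#' Simulates a mixed trace, detects and featurizes events, trains the SVM on
#' pure-class feature samples (the in-silico analog of training on pure
#' samples), classifies the detected events, and reports the digital count
#' ratio with its confidence interval. All outputs are reproducible from the
#' configuration and seed alone.
#'
#' @param config A `"run_config"` (path, list, or [default_run_config()]).
#' @param out_dir Optional directory for artifacts (`events.csv`,
#'   `summary.json`).
#' @return Summary list: counts, `R_NP` with CI, mass-percent conversion,
#'   seed, config hash, package version.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(config)
  labels <- names(cfg$mixture)
  classes <- lapply(labels, class_defaults)
  spec <- trace_spec(duration_s = cfg$trace$duration_s,
                     event_rate_hz = cfg$trace$event_rate_hz,
                     class_mixture = unlist(cfg$mixture),
                     open_pore_current_nA = cfg$trace$open_pore_current_nA,
                     baseline_noise_sd_nA = cfg$trace$baseline_noise_sd_nA,
                     sampling_rate_hz = cfg$trace$sampling_rate_hz,
                     voltage_mV = cfg$trace$voltage_mV,
                     seed = cfg$seed)
  sim <- synth_trace(spec, classes)
  bl <- estimate_baseline(sim$trace, cfg$detect$window_s)
  bounds <- detect_events(sim$trace, bl, cfg$detect$k_sigma,
                          cfg$detect$k_close, cfg$detect$min_dur_us,
                          cfg$detect$max_dur_us)
  feats <- extract_features(sim$trace, bounds, bl, cfg$detect$edge_frac)

  train_tabs <- lapply(seq_along(labels), function(i)
    sample_event_features(classes[[i]], cfg$classify$train_n_per_class,
                          seed = cfg$seed + i))
  train_fs <- build_features(do.call(rbind, train_tabs))
  train_fs <- balance_classes(train_fs, seed = cfg$seed)
  svm_cfg <- svm_config(cfg$classify$kernel_scale, cfg$classify$cost,
                        cfg$classify$n_folds, seed = cfg$seed)
  art <- train_svm(train_fs, svm_cfg)
  pred <- predict(art, feats)
  ratio <- compute_ratio(pred$label, cfg$quantify$positive_class)

  summary <- list(
    n_events_detected = nrow(feats),
    n_mt_events = ratio$n_mt_events,
    n_frag_events = ratio$n_frag_events,
    R_NP = ratio$R_NP, ci_low = ratio$ci_low, ci_high = ratio$ci_high,
    mass_ratio_percent = mass_ratio_percent(ratio$R_NP, cfg$quantify$kappa,
                                            cfg$quantify$mt_length_bp,
                                            cfg$quantify$genome_size_bp),
    seed = cfg$seed,
    config_hash = attr(config, "config_hash") %||% NA_character_,
    package_version = as.character(utils::packageVersion("mitopore")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    feats$predicted_label <- as.character(pred$label)
    write_events_csv(feats, file.path(out_dir, "events.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary
}
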