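#' Read observed concentration-time profiles from a NONMEM-style table
#'
#' Reads a delimited long-format dataset (one row per observation) with
#' columns for subject identifier, time after dose and measured
#' concentration.  Column names follow the NONMEM convention — `ID`,
#' `TIME`, `DV`, optional `AMT` (dose) and `WT` (weight) — matched
#' case-insensitively; `id`/`time`/`conc`/`dose`/`weight` (the layout
#' written by [write_dataset()]) are accepted as synonyms.  Each subject's
#' rows are matched against the design's sample times within a 0.01-h
#' tolerance; subjects missing any design time are excluded with reason
#' `"incomplete"`.  Rows at non-design times are ignored.
#'
#' @param path Path to a CSV file with a header.
#' @param design A [study_design()] giving the expected sample times.
#' @return List with `profiles` (a `pk_dataset`, unlabeled unless the
#'   file carries a `shape` column) and `exclusions` (data.frame of
#'   subject id and reason).
#' @export
read_profiles <- function(path, design = study_design()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- tolower(names(raw))
  pick <- function(aliases, required = TRUE) {
    hit <- which(cols %in% aliases)
    if (length(hit) == 0) {
      if (required) {
        stop(sprintf("missing required column (one of: %s)",
                     paste(toupper(aliases), collapse = ", ")))
      }
      return(NULL)
    }
    raw[[hit[1]]]
  }
  id <- as.character(pick(c("id", "subject", "subject_id")))
  time <- as.numeric(pick(c("time", "tad")))
  dv <- as.numeric(pick(c("dv", "conc", "concentration")))
  amt <- pick(c("amt", "dose"), required = FALSE)
  wt <- pick(c("wt", "weight"), required = FALSE)
  shape <- pick(c("shape", "label"), required = FALSE)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop(sprintf("non-numeric or negative TIME at row(s) %s",
                 paste(utils::head(which(!is.finite(time) | time < 0), 5),
                       collapse = ", ")))
  }
  dup <- duplicated(data.frame(id, time))
  if (any(dup)) {
    stop(sprintf("duplicate (ID, TIME) rows: %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")))
  }

  tt <- design$sample_times
  ids <- unique(id)
  kept <- list(); kept_id <- character(0); kept_shape <- character(0)
  excl <- data.frame(id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (s in ids) {
    rows <- which(id == s)
    # nearest design time within tolerance, per observation
    slot <- vapply(time[rows], function(tm) {
      j <- which.min(abs(tt - tm))
      if (abs(tt[j] - tm) <= 0.01) j else NA_integer_
    }, integer(1))
    conc <- rep(NA_real_, length(tt))
    conc[slot[!is.na(slot)]] <- dv[rows][!is.na(slot)]
    if (anyNA(conc)) {
      excl <- rbind(excl, data.frame(
        id = s,
        reason = sprintf("incomplete: missing time(s) %s",
                         paste(tt[is.na(conc)], collapse = ", "))))
      next
    }
    kept[[length(kept) + 1]] <- conc
    kept_id <- c(kept_id, s)
    kept_shape <- c(kept_shape,
                    if (is.null(shape)) NA_character_
                    else as.character(shape[rows[1]]))
  }
  conc_mat <- if (length(kept)) do.call(rbind, kept) else
    matrix(0, 0, length(tt))
  profiles <- structure(
    list(id = kept_id,
         shape = factor(kept_shape, levels = shape_levels()),
         conc = conc_mat,
         times = tt,
         dose = if (!is.null(amt)) as.numeric(amt[match(kept_id, id)])
                else design$dose,
         weight = if (!is.null(wt)) as.numeric(wt[match(kept_id, id)])
                  else design$weight,
         params = NULL),
    class = "pk_dataset")
  list(profiles = profiles, exclusions = excl)
}

#' Prescreen observed profiles with a trained classifier
#'
#' Feature-scales each profile and classifies it, producing a per-subject
#' report of the three absorption-shape probabilities, the assigned
#' label and a tie flag.  A profile that cannot be processed (e.g. a
#' degenerate flat profile) becomes an exclusion record rather than
#' aborting the batch, so every input subject appears exactly once —
#' either classified or excluded with a reason.
#'
#' @param profiles A `pk_dataset` (e.g. from [read_profiles()]).
#' @param model A trained `mlp` or the path to a saved model artifact.
#' @param exclusions Optional exclusion data.frame to carry through
#'   (e.g. from [read_profiles()]).
#' @return A `prescreen_report`: list with `classified` (data.frame: id,
#'   probabilities to 3 decimals, assigned, tie) and `exclusions`.
#' @export
prescreen <- function(profiles, model, exclusions = NULL) {
  if (is.character(model)) model <- load_model(model)
  excl <- if (is.null(exclusions)) {
    data.frame(id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  } else exclusions
  rows <- list()
  for (i in seq_along(profiles$id)) {
    res <- tryCatch({
      x <- feature_scale(profiles$conc[i, ])
      cl <- classify(model, x)
      data.frame(id = profiles$id[i],
                 p_first_order = round(cl$p_first_order, 3),
                 p_erlang = round(cl$p_erlang, 3),
                 p_split_peak = round(cl$p_split_peak, 3),
                 assigned = as.character(cl$assigned),
                 tie = cl$tie,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl <- rbind(excl, data.frame(id = profiles$id[i], reason = res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  classified <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), p_first_order = numeric(0),
               p_erlang = numeric(0), p_split_peak = numeric(0),
               assigned = character(0), tie = logical(0))
  structure(list(classified = classified, exclusions = excl),
            class = "prescreen_report")
}

#' @export
print.prescreen_report <- function(x, ...) {
  cat(sprintf("Prescreen report: %d classified, %d excluded\n",
              nrow(x$classified), nrow(x$exclusions)))
  if (nrow(x$classified)) print(utils::head(x$classified, 10))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param n_per_shape Simulated profiles per absorption shape.
#' @param holdout_fraction Validation fraction of the simulated set.
#' @param hidden Hidden-layer widths.
#' @param batch_size,epochs Training settings.
#' @param seed Master seed for the whole run.
#' @param n_transit Erlang transit compartments.
#' @return Named list of settings consumed by [run_pipeline()].
#' @export
pipeline_config <- function(n_per_shape = 10000L, holdout_fraction = 0.3,
                            hidden = c(64L, 64L, 64L), batch_size = 32L,
                            epochs = 100L, seed = 2021L, n_transit = 8L) {
  list(n_per_shape = n_per_shape, holdout_fraction = holdout_fraction,
       hidden = hidden, batch_size = batch_size, epochs = epochs,
       seed = seed, n_transit = n_transit)
}

#' Run the simulate -> split -> train -> evaluate pipeline
#'
#' Executes the four stages from one master seed (sub-seeds are spawned
#' per stage, see [spawn_seeds()]) and, if `out_dir` is given, writes the
#' dataset, model artifact, per-epoch history, confusion matrix and a
#' summary table of n / accuracy / loss per data split.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file
#'   holding (a subset of) its fields.
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Print training progress.
#' @return List with `dataset`, `split`, `net`, `history`, `report`
#'   (validation [evaluate_model()] report) and `summary` (data.frame of
#'   n, accuracy and loss for the training and validation splits).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(pipeline_config(), user)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- spawn_seeds(config$seed, 4L)
  pop <- population_parameters(n_transit = config$n_transit)
  design <- study_design()

  ds <- stage("simulate",
              simulate_dataset(pop, design, config$n_per_shape, seeds[1]))
  sp <- stage("split", stratified_split(ds, config$holdout_fraction, seeds[2]))
  tr <- stage("train", {
    ftr <- assemble_features(sp$train)
    fva <- assemble_features(sp$validation)
    net <- init_network(c(ncol(ftr$x), config$hidden, 3L), seed = seeds[3])
    cfg <- training_config(batch_size = config$batch_size,
                           epochs = config$epochs, seed = seeds[4])
    train_network(net, ftr$x, ftr$y, fva$x, fva$y, cfg, verbose = verbose)
  })
  report <- stage("evaluate", evaluate_model(tr$net, sp$validation))
  last <- tr$history[nrow(tr$history), ]
  summary <- data.frame(
    data = c("Training", "Validation"),
    n = c(length(sp$train$id), length(sp$validation$id)),
    accuracy_pct = round(100 * c(last$train_acc, last$val_acc), 1),
    loss = signif(c(last$train_loss, last$val_loss), 3))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      write_dataset(ds, file.path(out_dir, "simulated_profiles.csv"))
      save_model(tr$net, file.path(out_dir, "model.json"))
      utils::write.csv(tr$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame.matrix(report$confusion),
                       file.path(out_dir, "confusion.csv"))
      yaml::write_yaml(list(seed = config$seed, config = config,
                            r_version = as.character(getRversion())),
                       file.path(out_dir, "run_metadata.yaml"))
    })
  }
  list(dataset = ds, split = sp, net = tr$net, history = tr$history,
       report = report, summary = summary)
}
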