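# Seeded end-to-end experiment driver: noise grid x methods -> accuracy table.

#' Experiment configuration
#'
#' Describes a full benchmark grid: a phantom, a set of noise kinds and
#' levels, a replicate count, the ensemble composition and the consensus
#' settings. [run_experiment()] consumes this object; it can also be
#' round-tripped through a flat key=value text file with
#' [write_experiment_config()] / [read_experiment_config()].
#'
#' @param phantom `"two_value"` or `"trin"`.
#' @param noise Named list mapping noise kind (`gaussian`, `rician`) to a
#'   numeric vector of percentage levels.
#' @param replicates Number of replicates per (kind, level) cell.
#' @param seed Master integer seed; every per-cell seed is derived from it
#'   and recorded in the output.
#' @param clusters Number of segments; defaults to the phantom's region count.
#' @param size Phantom side length; defaults to the phantom's standard size.
#' @param members Base clusterer specs (see [default_members()]).
#' @param m,window,tol,max_iter Consensus and member settings.
#' @param methods Which methods to score: any of `"members"`, `"fce_kl"`,
#'   `"fce_skl"`.
#' @return An object of class `klfce_experiment_config`.
#' @export
experiment_config <- function(phantom = c("two_value", "trin"),
                              noise = list(gaussian = c(5, 20)),
                              replicates = 5, seed = 1,
                              clusters = NULL, size = NULL,
                              members = default_members(),
                              m = 2, window = 5, tol = 1e-5, max_iter = 100,
                              methods = c("members", "fce_kl", "fce_skl")) {
  phantom <- match.arg(phantom)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.list(noise) || is.null(names(noise)) ||
      !all(names(noise) %in% c("gaussian", "rician"))) {
    stop("noise must be a named list with elements 'gaussian' and/or 'rician'", call. = FALSE)
  }
  structure(
    list(phantom = phantom,
         size = size %||% switch(phantom, two_value = 50, trin = 64),
         clusters = clusters %||% switch(phantom, two_value = 2, trin = 4),
         noise = noise, replicates = as.integer(replicates),
         seed = as.integer(seed), members = members,
         m = m, window = window, tol = tol, max_iter = max_iter,
         methods = methods),
    class = "klfce_experiment_config"
  )
}

.make_phantom <- function(cfg) {
  switch(cfg$phantom,
         two_value = make_two_value_phantom(cfg$size),
         trin = make_trin_phantom(cfg$size))
}

.cell_sa <- function(U, dims, truth) {
  segmentation_accuracy(align_labels(defuzzify(U, dims), truth), truth)
}

#' Run a seeded benchmark experiment
#'
#' For every (noise kind, level, replicate) cell: corrupt the clean phantom
#' once with a derived per-cell seed, run every configured method on that
#' same noisy image (single-image fairness), defuzzify, align labels to the
#' ground truth and record the overall segmentation accuracy. A failing cell
#' is recorded with `sa = NA` and the error message in `note`; the run
#' continues.
#'
#' @param cfg An [experiment_config()].
#' @return Long-format data frame with columns `phantom`, `kind`, `level`,
#'   `replicate`, `seed`, `method`, `sa`, `note`. The per-cell mean/sd
#'   summary from [summarize_experiment()] is attached as attribute
#'   `"summary"`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "klfce_experiment_config"))
  ph <- .make_phantom(cfg)
  dims <- dim(ph$image)
  rows <- list()
  cell <- 0L
  for (kind in names(cfg$noise)) {
    for (level in cfg$noise[[kind]]) {
      for (rep in seq_len(cfg$replicates)) {
        cell <- cell + 1L
        cell_seed <- derive_seed(cfg$seed, cell)
        res <- tryCatch({
          noisy <- switch(kind,
                          gaussian = add_gaussian_noise(ph, level, seed = cell_seed),
                          rician = add_rician_noise(ph, level, seed = cell_seed))
          sas <- c()
          parts <- generate_basic_partitions(noisy, cfg$clusters, cfg$members,
                                             m = cfg$m, max_iter = cfg$max_iter,
                                             tol = cfg$tol,
                                             seed = derive_seed(cell_seed, 1))
          if ("members" %in% cfg$methods) {
            for (nm in names(parts)) sas[nm] <- .cell_sa(parts[[nm]], dims, ph$labels)
          }
          Y <- concatenate_normalize(parts)
          consensus_seed <- derive_seed(cell_seed, 2)
          if ("fce_kl" %in% cfg$methods) {
            fit <- fce_kl_fit(Y, cfg$clusters, m = cfg$m, max_iter = cfg$max_iter,
                              tol = cfg$tol, seed = consensus_seed)
            sas["fce_kl"] <- .cell_sa(fit$memberships, dims, ph$labels)
          }
          if ("fce_skl" %in% cfg$methods) {
            fit <- fce_skl_fit(Y, dims, cfg$clusters, m = cfg$m,
                               window = cfg$window, max_iter = cfg$max_iter,
                               tol = cfg$tol, seed = consensus_seed)
            sas["fce_skl"] <- .cell_sa(fit$memberships, dims, ph$labels)
          }
          data.frame(phantom = cfg$phantom, kind = kind, level = level,
                     replicate = rep, seed = cell_seed,
                     method = names(sas), sa = unname(sas), note = "",
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(phantom = cfg$phantom, kind = kind, level = level,
                     replicate = rep, seed = cell_seed,
                     method = "all", sa = NA_real_,
                     note = conditionMessage(e), stringsAsFactors = FALSE)
        })
        rows[[cell]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- summarize_experiment(out)
  out
}

#' Per-cell summary of an experiment table
#'
#' @param table Long-format table from [run_experiment()].
#' @return Data frame of mean and sd of accuracy per
#'   (phantom, kind, level, method).
#' @export
summarize_experiment <- function(table) {
  ok <- !is.na(table$sa)
  agg <- aggregate(sa ~ phantom + kind + level + method, data = table[ok, ],
                   FUN = function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0))
  out <- data.frame(agg[c("phantom", "kind", "level", "method")],
                    mean_sa = agg$sa[, "mean"], sd_sa = agg$sa[, "sd"])
  out[order(out$kind, out$level, out$method), , drop = FALSE]
}

#' Write an experiment configuration as a flat key=value file
#'
#' Member specs are serialised as `method:window` tokens (window omitted for
#' plain fcm). The format is the one [read_experiment_config()] parses.
#'
#' @param cfg An [experiment_config()].
#' @param path Destination path.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "klfce_experiment_config"))
  member_tok <- vapply(cfg$members, function(sp) {
    if (identical(sp$method, "sfcm")) paste0("sfcm:", sp$window %||% 3) else sp$method
  }, character(1))
  lines <- c(
    paste0("phantom=", cfg$phantom),
    paste0("size=", cfg$size),
    paste0("clusters=", cfg$clusters),
    paste0("gaussian_levels=", paste(cfg$noise$gaussian %||% numeric(0), collapse = ",")),
    paste0("rician_levels=", paste(cfg$noise$rician %||% numeric(0), collapse = ",")),
    paste0("replicates=", cfg$replicates),
    paste0("seed=", cfg$seed),
    paste0("members=", paste(member_tok, collapse = ",")),
    paste0("m=", cfg$m),
    paste0("window=", cfg$window),
    paste0("tol=", cfg$tol),
    paste0("max_iter=", cfg$max_iter),
    paste0("methods=", paste(cfg$methods, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' @param path Path to a key=value file written by
#'   [write_experiment_config()] (or by hand in the same schema).
#' @return An [experiment_config()] object.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config: '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get <- function(k, default = NULL) if (k %in% keys) vals[[match(k, keys)]] else default
  nums <- function(s) if (is.null(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ",")[[1]])
  opt_int <- function(k) {
    v <- get(k)
    if (is.null(v)) NULL else as.integer(v)
  }
  members <- lapply(strsplit(get("members", "fcm,fcm,sfcm:3,sfcm:5"), ",")[[1]], function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (parts[1] == "sfcm") list(method = "sfcm", window = as.numeric(parts[2] %||% 3))
    else list(method = parts[1])
  })
  names(members) <- make.unique(vapply(members, function(sp) {
    if (identical(sp$method, "sfcm")) paste0("sfcm_w", sp$window) else sp$method
  }, character(1)), sep = "_")
  noise <- list()
  g <- nums(get("gaussian_levels"))
  r <- nums(get("rician_levels"))
  if (length(g)) noise$gaussian <- g
  if (length(r)) noise$rician <- r
  experiment_config(
    phantom = get("phantom", "two_value"),
    noise = noise,
    replicates = as.integer(get("replicates", "5")),
    seed = as.integer(get("seed", "1")),
    clusters = opt_int("clusters"),
    size = opt_int("size"),
    members = members,
    m = as.numeric(get("m", "2")),
    window = as.numeric(get("window", "5")),
    tol = as.numeric(get("tol", "1e-5")),
    max_iter = as.integer(get("max_iter", "100")),
    methods = strsplit(get("methods", "members,fce_kl,fce_skl"), ",")[[1]]
  )
}
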