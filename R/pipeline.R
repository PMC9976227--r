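#' End-to-end pipeline: config, staged run, change report, manifest
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' Exactly one input mode is active: `files` (paths to the flow and
#' indicator CSVs) or `synthetic` (a named list year -> [world_config()]).
#'
#' @param files NULL or list(flows = path, indicators = path).
#' @param synthetic NULL or named list of `world_config`s, names = years.
#' @param years one or two calendar years; with two, a change report
#'   comparing them is produced.
#' @param threshold USD binarization threshold.
#' @param classifier component-grade classifier, `"jenks"` or
#'   `"equal_interval"`.
#' @param rici_mode `"partner_cri"` or `"own_cri"`.
#' @param aecsi_mode `"raw"` or `"graded"`.
#' @param theta absolute-dependence share threshold.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (community detection; logged in the manifest).
#' @return a `run_config` list.
#' @export
run_config <- function(files = NULL, synthetic = NULL, years,
                       threshold = 1e8,
                       classifier = c("jenks", "equal_interval"),
                       rici_mode = c("partner_cri", "own_cri"),
                       aecsi_mode = c("raw", "graded"),
                       theta = 0.5, out_dir = tempfile("risknet_run_"),
                       seed = 1L) {
  if (is.null(files) == is.null(synthetic)) {
    stop("run_config: exactly one of files / synthetic must be given",
         call. = FALSE)
  }
  if (!is.null(files)) {
    for (p in unlist(files)) {
      if (!file.exists(p)) stop("run_config: no such file: ", p,
                                call. = FALSE)
    }
  }
  structure(list(files = files, synthetic = synthetic,
                 years = as.integer(years), threshold = threshold,
                 classifier = match.arg(classifier),
                 rici_mode = match.arg(rici_mode),
                 aecsi_mode = match.arg(aecsi_mode),
                 theta = theta, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# strip S3 classes recursively so nested config objects serialize plainly
.unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .unclass_deep))
  x
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL  # output location must not change the run identity
  .write_json(.unclass_deep(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Per year: network metrics (JSON summary, degree CSV), export/import
#' share CSVs, Louvain partition CSV + community summary JSON, the risk
#' table CSV with its break-set JSON, and dependence pairs. With two years,
#' a change report (density/edge deltas, AECSI grade-migration counts). A
#' failing stage is recorded in the manifest and its dependents are
#' skipped; independent stages still run.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run.
#' @return the manifest list, invisibly; all artefacts are files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config,
                         stages = c("network", "shares", "communities",
                                    "risk", "report")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(config = .unclass_deep(config),
                   config_hash = .config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("supplynet")),
                   stages = list(), outputs = character(0))
  log_stage <- function(name, status, note = "") {
    manifest$stages[[name]] <<- list(status = status, note = note)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    name, status))
  }
  add_out <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  run_stage <- function(name, dep_ok = TRUE, expr) {
    if (!dep_ok) {
      log_stage(name, "skipped", "upstream failure")
      return(NULL)
    }
    tryCatch({
      r <- force(expr)
      log_stage(name, "ok")
      r
    }, error = function(e) {
      log_stage(name, "failed", conditionMessage(e))
      NULL
    })
  }

  # inputs: flows feed every stage; indicators only the risk stage, so a
  # broken indicator file must not take the network stages down with it
  worlds <- NULL
  inputs <- run_stage("inputs", TRUE, {
    if (!is.null(config$files)) {
      list(flows = load_trade_flows(config$files$flows))
    } else {
      # the stage expression evaluates in this function frame, so plain
      # assignment reaches the local `worlds`
      worlds <- lapply(names(config$synthetic), function(y) {
        generate_world(config$synthetic[[y]], year = as.integer(y))
      })
      list(flows = trade_flows(do.call(rbind, lapply(
        worlds, function(w) as.data.frame(w$flows)))))
    }
  })
  if (is.null(inputs)) {
    .write_json(manifest, file.path(config$out_dir, "manifest.json"))
    return(invisible(manifest))
  }
  indicators <- run_stage("indicators", TRUE, {
    if (!is.null(config$files)) load_indicators(config$files$indicators)
    else do.call(rbind, lapply(worlds, `[[`, "indicators"))
  })
  inputs$indicators <- indicators

  risk_tables <- list()
  net_summaries <- list()
  for (y in config$years) {
    ytag <- as.character(y)
    net <- run_stage(paste0("network_", ytag), "network" %in% stages, {
      net <- binarize(build_network(inputs$flows, y), config$threshold)
      s <- network_summary(net)
      .write_json(s, add_out(file.path(config$out_dir,
                                       sprintf("network_%d.json", y))))
      utils::write.csv(degrees(net),
                       add_out(file.path(config$out_dir,
                                         sprintf("degrees_%d.csv", y))),
                       row.names = FALSE)
      net_summaries[[ytag]] <- s
      net
    })
    run_stage(paste0("shares_", ytag), "shares" %in% stages, {
      for (dirn in c("export", "import")) {
        sh <- trade_shares(inputs$flows, y, direction = dirn)
        utils::write.csv(sh, add_out(file.path(
          config$out_dir, sprintf("shares_%s_%d.csv", dirn, y))),
          row.names = FALSE)
      }
    })
    run_stage(paste0("communities_", ytag),
              ("communities" %in% stages) && !is.null(net), {
      part <- louvain(net, weighted = TRUE, seed = config$seed,
                      rescale = TRUE)
      utils::write.csv(data.frame(iso3 = names(part$assignment),
                                  community_id = unname(part$assignment)),
                       add_out(file.path(config$out_dir,
                                         sprintf("partition_%d.csv", y))),
                       row.names = FALSE)
      .write_json(list(n_communities = part$n_communities,
                       sizes = part$sizes, q = part$q),
                  add_out(file.path(config$out_dir,
                                    sprintf("communities_%d.json", y))))
      dp <- dependence_pairs(inputs$flows, y, theta = config$theta)
      dp$theta <- rep(config$theta, nrow(dp))
      utils::write.csv(dp, add_out(file.path(
        config$out_dir, sprintf("dependence_%d.csv", y))),
        row.names = FALSE)
    })
    rk <- run_stage(paste0("risk_", ytag),
                    ("risk" %in% stages) && !is.null(indicators), {
      rk <- risk_pipeline(inputs$flows, inputs$indicators, y,
                          classifier = config$classifier,
                          rici_mode = config$rici_mode,
                          aecsi_mode = config$aecsi_mode)
      utils::write.csv(rk, add_out(file.path(config$out_dir,
                                             sprintf("risk_%d.csv", y))),
                       row.names = FALSE)
      br <- attr(rk, "breaks")
      .write_json(lapply(br, function(b) {
        if (is.null(b)) NULL
        else list(method = b$method, k = b$k, edges = b$edges)
      }),
                  add_out(file.path(config$out_dir,
                                    sprintf("breaks_%d.json", y))))
      rk
    })
    if (!is.null(rk)) risk_tables[[ytag]] <- rk
  }

  if ("report" %in% stages && length(config$years) == 2L) {
    y1 <- as.character(config$years[1]); y2 <- as.character(config$years[2])
    dep_ok <- !is.null(net_summaries[[y1]]) && !is.null(net_summaries[[y2]])
    run_stage("change_report", dep_ok, {
      s1 <- net_summaries[[y1]]; s2 <- net_summaries[[y2]]
      rep <- list(years = config$years,
                  delta_edges = s2$E - s1$E,
                  delta_density = s2$density - s1$density)
      if (!is.null(risk_tables[[y1]]) && !is.null(risk_tables[[y2]])) {
        m <- merge(risk_tables[[y1]][c("country", "grade_aecsi", "aecsi")],
                   risk_tables[[y2]][c("country", "grade_aecsi", "aecsi")],
                   by = "country", suffixes = c("_from", "_to"))
        mig <- table(from = m$grade_aecsi_from, to = m$grade_aecsi_to)
        rep$grade_migration <- as.data.frame(mig, stringsAsFactors = FALSE)
        rep$mean_aecsi <- c(mean(risk_tables[[y1]]$aecsi),
                            mean(risk_tables[[y2]]$aecsi))
      }
      .write_json(rep, add_out(file.path(config$out_dir,
                                         "change_report.json")))
    })
  }

  manifest$wall_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$output_md5 <- as.list(tools::md5sum(
    file.path(config$out_dir, sort(unique(manifest$outputs)))))
  names(manifest$output_md5) <- basename(names(manifest$output_md5))
  .write_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `network`, `communities`, `risk`, `report`,
#' `all`. Flags: `--flows`, `--indicators` (file mode), `--years` (comma
#' separated), `--threshold`, `--classifier`, `--rici-mode`,
#' `--aecsi-mode`, `--theta`, `--out`, `--seed`, and `--synthetic` to run
#' on a generated world instead of files.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return the manifest, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: supplynet <simulate|network|communities|risk|report|all> ",
         "[--flows F --indicators I | --synthetic] [--years Y1[,Y2]] ",
         "[--threshold T] [--classifier jenks|equal] ",
         "[--rici-mode partner|own] [--aecsi-mode raw|graded] ",
         "[--theta TH] [--seed S] --out DIR", call. = FALSE)
  }
  sub <- args[1L]
  opt <- list(years = "2019,2021", threshold = "1e8", classifier = "jenks",
              `rici-mode` = "partner", `aecsi-mode` = "raw", theta = "0.5",
              seed = "1", out = "supplynet_out", flows = NULL,
              indicators = NULL, synthetic = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--synthetic") { opt$synthetic <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--")) stop("unknown argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  years <- as.integer(strsplit(opt$years, ",")[[1L]])
  seed <- as.integer(opt$seed)

  if (isTRUE(opt$synthetic)) {
    synth <- stats::setNames(lapply(seq_along(years), function(j) {
      world_config(cri_regime = if (j == 1L) "pre_epidemic" else "epidemic",
                   seed = seed + j - 1L)
    }), years)
    files <- NULL
  } else {
    if (is.null(opt$flows) || is.null(opt$indicators)) {
      stop("file mode needs --flows and --indicators (or use --synthetic)",
           call. = FALSE)
    }
    files <- list(flows = opt$flows, indicators = opt$indicators)
    synth <- NULL
  }
  cfg <- run_config(files = files, synthetic = synth, years = years,
                    threshold = as.numeric(opt$threshold),
                    classifier = if (opt$classifier == "equal")
                      "equal_interval" else opt$classifier,
                    rici_mode = paste0(sub("_cri$", "",
                                           opt$`rici-mode`), "_cri"),
                    aecsi_mode = opt$`aecsi-mode`,
                    theta = as.numeric(opt$theta),
                    out_dir = opt$out, seed = seed)

  if (sub == "simulate") {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(cfg$synthetic)) stop("simulate requires --synthetic",
                                     call. = FALSE)
    for (y in names(cfg$synthetic)) {
      w <- generate_world(cfg$synthetic[[y]], year = as.integer(y))
      utils::write.csv(data.frame(year = w$flows$year,
                                  exporter_iso3 = w$flows$exporter,
                                  importer_iso3 = w$flows$importer,
                                  value_usd = w$flows$value),
                       file.path(cfg$out_dir, sprintf("flows_%s.csv", y)),
                       row.names = FALSE)
      utils::write.csv(w$indicators,
                       file.path(cfg$out_dir,
                                 sprintf("indicators_%s.csv", y)),
                       row.names = FALSE)
    }
    return(invisible(cfg))
  }
  stages <- switch(sub,
                   network = c("network", "shares"),
                   communities = c("network", "communities"),
                   risk = "risk",
                   report = c("network", "risk", "report"),
                   all = c("network", "shares", "communities", "risk",
                           "report"),
                   stop("unknown subcommand: ", sub, call. = FALSE))
  run_pipeline(cfg, stages = stages)
}
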