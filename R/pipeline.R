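# End-to-end pipeline: simulate (or ingest) -> value -> monetize ->
# decompose -> project -> bootstrap, with all intermediate tables written to
# an output directory and a JSON summary of the headline quantities.

#' Pipeline run configuration
#'
#' Either builds a configuration programmatically or loads one from a YAML
#' file (keys mirror the arguments; CLI flags and explicit arguments
#' override file keys).
#'
#' @param world A \code{\link{world_config}} used when no input files are
#'   given.
#' @param causes Cause labels to analyse.
#' @param inputs Optional list of file paths: \code{dalys} (one or more
#'   GBD-dialect CSVs), \code{econ}, \code{demog}, \code{pop_age} (tidy
#'   panel CSVs). When NULL, a synthetic world is generated.
#' @param vsl A \code{\link{vsl_params}}.
#' @param bootstrap A \code{\link{bootstrap_config}}.
#' @param engine Projection engine, \code{"scenario"} or \code{"bapc"}.
#' @param scenario Scenario name for the scenario engine.
#' @param projection_years Years to project burden for.
#' @param decompose_years Length-2: decomposition start and end year;
#'   default the world's year range.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; propagates to every stochastic stage.
#' @param yaml_path Optional YAML file with the same keys.
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(world = world_config(), causes = c("Leukemia"),
                       inputs = NULL, vsl = vsl_params(),
                       bootstrap = bootstrap_config(),
                       engine = c("scenario", "bapc"),
                       scenario = "baseline",
                       projection_years = c(2030, 2040, 2050),
                       decompose_years = NULL,
                       out_dir = tempfile("hemecon_run_"),
                       seed = 1L, yaml_path = NULL) {
  engine <- match.arg(engine)
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) stop("config file not found: ", yaml_path)
    y <- yaml::read_yaml(yaml_path)
    if (!is.null(y$causes)) causes <- y$causes
    if (!is.null(y$engine)) engine <- y$engine
    if (!is.null(y$scenario)) scenario <- y$scenario
    if (!is.null(y$projection_years)) projection_years <- y$projection_years
    if (!is.null(y$decompose_years)) decompose_years <- y$decompose_years
    if (!is.null(y$out_dir)) out_dir <- y$out_dir
    if (!is.null(y$seed)) seed <- y$seed
    if (!is.null(y$inputs)) inputs <- y$inputs
    if (!is.null(y$world))
      world <- do.call(world_config, y$world)
    if (!is.null(y$vsl)) vsl <- do.call(vsl_params, y$vsl)
    if (!is.null(y$bootstrap)) bootstrap <- do.call(bootstrap_config,
                                                    y$bootstrap)
  }
  if (!is.null(inputs)) {
    paths <- unlist(inputs, use.names = FALSE)
    missing_p <- paths[!file.exists(paths)]
    if (length(missing_p))
      stop("input path(s) not found: ", paste(missing_p, collapse = ", "))
  }
  if (is.null(decompose_years)) decompose_years <- world$years
  structure(list(world = world, causes = causes, inputs = inputs,
                 vsl = vsl, bootstrap = bootstrap, engine = engine,
                 scenario = scenario, projection_years = projection_years,
                 decompose_years = decompose_years, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, valuation, monetization, decomposition,
#' projection and bootstrap, writing every intermediate table as CSV under
#' \code{config$out_dir} and a JSON summary of the headline quantities
#' (totals, income-group shares, percent change, GDP share, decomposition
#' percentages, projected burdens, bootstrap intervals). Stage timings and
#' seeds are logged via \code{message()}.
#'
#' @param config A \code{\link{run_config}}.
#' @param quiet Suppress stage log messages.
#' @return The summary list, invisibly; also written to
#'   \code{out_dir/summary.json}.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, t0) if (!quiet)
    message(sprintf("[%s] done in %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say(name, t0)
    out
  }

  dat <- stage("simulate/ingest", {
    if (is.null(config$inputs)) {
      wc <- config$world
      wc$seed <- config$seed
      world <- gen_world(wc, causes = config$causes)
      dalys <- do.call(rbind, lapply(seq_along(config$causes), function(i)
        gen_daly_table(world, config$causes[i],
                       seed = config$seed + 1000L + i)))
      list(econ = world$econ, demog = world$demog,
           pop_age = world$pop_age, dalys = dalys)
    } else {
      dalys <- do.call(rbind, lapply(config$inputs$dalys, read_gbd_csv))
      econ <- utils::read.csv(config$inputs$econ, stringsAsFactors = FALSE)
      demog <- utils::read.csv(config$inputs$demog, stringsAsFactors = FALSE)
      pop_age <- if (!is.null(config$inputs$pop_age))
        utils::read.csv(config$inputs$pop_age, stringsAsFactors = FALSE)
      list(econ = econ, demog = demog, pop_age = pop_age, dalys = dalys)
    }
  })
  write_panel_csv(dat$econ, file.path(config$out_dir, "econ.csv"))
  write_panel_csv(dat$demog, file.path(config$out_dir, "demog.csv"))
  write_gbd_csv(dat$dalys, file.path(config$out_dir, "dalys.csv"))

  vsly <- stage("value", build_vsly_table(dat$econ, dat$demog, config$vsl))
  write_panel_csv(vsly, file.path(config$out_dir, "vsly.csv"))

  burden <- stage("monetize", monetize(dat$dalys, vsly, config$vsl))
  write_panel_csv(burden, file.path(config$out_dir, "burden.csv"))

  y0 <- config$decompose_years[1]; y1 <- config$decompose_years[2]
  total0 <- aggregate_burden(burden, "global", year = y0)$burden
  total1 <- aggregate_burden(burden, "global", year = y1)$burden
  by_grp <- aggregate_burden(burden, "income_group", year = y1,
                             econ = dat$econ)
  by_cause <- aggregate_burden(burden, "cause", year = y1)
  gdp1 <- sum(dat$econ$gdp[dat$econ$year == y1])

  decomp <- stage("decompose", {
    countries <- unique(burden$country)
    per_country <- lapply(countries, function(co) {
      s0 <- factor_state_from_tables(co, y0, dat$pop_age, dat$dalys, vsly)
      s1 <- factor_state_from_tables(co, y1, dat$pop_age, dat$dalys, vsly)
      shapley_decompose(s0, s1)
    })
    aggregate_decomposition(per_country)
  })
  utils::write.csv(decomp$table,
                   file.path(config$out_dir, "decomposition.csv"),
                   row.names = FALSE)

  proj <- stage("project", {
    spec <- scenario_spec(config$scenario, anchor_year = y1)
    ages <- unique(dat$pop_age$age)
    proj_by_country <- lapply(unique(burden$country), function(co) {
      st <- factor_state_from_tables(co, y1, dat$pop_age, dat$dalys, vsly)
      e_co <- dat$econ[dat$econ$country == co, ]
      win <- c(max(min(e_co$year), 2011), min(max(e_co$year), 2020))
      if (win[2] <= win[1]) win <- range(e_co$year)
      gr <- gni_growth_rate(stats::setNames(e_co$gnipc, e_co$year), win)
      rows <- lapply(config$projection_years, function(t) {
        r_t <- scenario_rates(st$r, spec, t)
        dal <- sum(st$P * st$s * r_t)     # population held at end-year pyramid
        v_t <- project_vsly(st$V, gr, t, base_year = y1)
        data.frame(country = co, year = t, dalys = dal,
                   burden = discount_to_base(dal * v_t, t, config$vsl))
      })
      do.call(rbind, rows)
    })
    do.call(rbind, proj_by_country)
  })
  write_panel_csv(proj, file.path(config$out_dir, "projection.csv"))

  boot <- stage("bootstrap", {
    grp <- dat$econ$income_group[dat$econ$year == y1]
    names(grp) <- dat$econ$country[dat$econ$year == y1]
    cfg <- config$bootstrap
    cfg$seed <- config$seed + 2L
    bootstrap_burden(dat$dalys, vsly, cfg, strata = grp, year = y1)
  })
  utils::write.csv(boot, file.path(config$out_dir, "bootstrap.csv"),
                   row.names = FALSE)

  shares <- share_of_total(by_grp$burden, total1)
  summary <- list(
    seed = config$seed,
    years = c(y0, y1),
    total_burden = stats::setNames(c(total0, total1),
                                   paste0("y", c(y0, y1))),
    percent_change = percent_change(total0, total1),
    income_group_share = stats::setNames(as.list(shares),
                                         by_grp$income_group),
    cause_share = stats::setNames(
      as.list(share_of_total(by_cause$burden, total1)), by_cause$cause),
    gdp_share_percent = 100 * gdp_share(total1, gdp1),
    decomposition_percent = stats::setNames(
      as.list(decomp$table$percent), decomp$table$factor),
    projected_burden = stats::setNames(
      as.list(tapply(proj$burden, proj$year, sum)),
      paste0("y", sort(unique(proj$year)))),
    bootstrap = boot)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
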