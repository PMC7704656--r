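#' Default pipeline configuration
#'
#' Defaults: `ndiv = 32`, `nref = 0`, continuous `beta = 1.1` (branched
#' regime), uniform `mu0`, extraction rule I with ER at `delta = 0.01`,
#' `tau_bc = 0.1`, filter `beta_d = 1.1` with `delta_d = 1e-3` and BPW
#' weights, metric `q = 2` on an `N = 11` partition (100 cells). Every field
#' can be overridden.
#'
#' @param forcing a [forcing_spec()].
#' @param ... named overrides of the nested defaults (e.g.
#'   `mesh = list(ndiv = 16)`, `continuous = list(beta = 1.2)`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(forcing, ...) {
  cfg <- list(
    mesh = list(ndiv = 32L, nref = 0L),
    forcing = forcing,
    continuous = list(beta = 1.1, mu0 = "uniform", dt = 0.1, tol = 1e-4,
                      max_iter = 2000L),
    extraction = list(rule = "I", weight_rule = "ER", delta = 0.01),
    terminals = list(tau_bc = 0.1),
    filter = list(beta_d = 1.1, delta_d = 1e-3, weight_mode = "BPW"),
    metrics = list(q = 2, partition_N = 11L),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Initial conductivity families
#'
#' Three families of initial transport densities on a mesh:
#' * `"uniform"`: \eqn{\mu_0 \equiv 1};
#' * `"parabola"`: a parabola-like bump centred in the domain,
#'   \eqn{\mu_0 = 0.05 + \max(0, 1 - 8 r^2)} with `r` the distance of the
#'   barycenter from (0.5, 0.5);
#' * `"delta"`: a delta-like concentrated Gaussian peak of width 0.05 at the
#'   centre, floored at 0.05.
#'
#' The floors keep \eqn{\mu_0 > 0} everywhere, as the dynamics requires.
#'
#' @param mesh a `tri_mesh`.
#' @param family `"uniform"`, `"parabola"` or `"delta"`, or a numeric vector.
#' @return per-triangle initial conductivity.
#' @export
mu0_family <- function(mesh, family = "uniform") {
  if (is.numeric(family)) return(rep_len(family, nrow(mesh$triangles)))
  r2 <- (mesh$barycenters[, 1] - 0.5)^2 + (mesh$barycenters[, 2] - 0.5)^2
  switch(match.arg(family, c("uniform", "parabola", "delta")),
         uniform = rep(1, nrow(mesh$triangles)),
         parabola = 0.05 + pmax(0, 1 - 8 * r2),
         delta = pmax(exp(-r2 / (2 * 0.05^2)), 0.05))
}

#' Run the full extraction pipeline
#'
#' Executes the three-stage protocol: continuous dynamical Monge-Kantorovich
#' solve, rule-based graph pre-extraction, terminal selection plus discrete
#' Monge-Kantorovich filtering, and evaluation metrics. When `out_dir` is
#' given all stage artefacts (solution tables, graphs as TSV and GraphML,
#' terminal report, energy report, metric report) and a JSON run manifest
#' are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `mesh`, `forcing`, `solution` (`dmk_continuous`),
#'   `pregraph`, `terminals`, `filter_result` (`dmk_discrete`), `filtered`
#'   (igraph), `metrics` (list: `w_hat` report, `length`, `vein_lengths`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)),
      warning = function(w) {
        warning(sprintf("[%s] %s", name, conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      })
  }
  mesh <- stage("mesh", build_structured_mesh(config$mesh$ndiv, config$mesh$nref))
  f <- stage("forcing", evaluate_forcing(mesh, config$forcing))
  mu0 <- mu0_family(mesh, config$continuous$mu0)
  solution <- stage("continuous-dmk", run_continuous_dmk(
    mesh, f, mu0 = mu0, beta = config$continuous$beta, dt = config$continuous$dt,
    tol = config$continuous$tol, max_iter = config$continuous$max_iter))
  pregraph <- stage("pre-extraction", pre_extract(
    mesh, solution, delta = config$extraction$delta, rule = config$extraction$rule,
    weight_rule = config$extraction$weight_rule))
  terminals <- stage("terminals", {
    elig <- eligible_nodes(pregraph, config$forcing)
    sel <- select_terminals(pregraph, elig, tau_bc = config$terminals$tau_bc)
    assign_fluxes(pregraph, sel$sources, sel$sinks)
  })
  flt <- stage("filter", filter_graph(
    pregraph, terminals, beta_d = config$filter$beta_d,
    delta_d = config$filter$delta_d, mode = config$filter$weight_mode))
  metrics <- stage("metrics", {
    part <- domain_partition(config$metrics$partition_N)
    list(w_hat = local_weight_metric(flt$graph, solution, mesh,
                                     delta = config$extraction$delta,
                                     partition = part, q = config$metrics$q),
         length = total_length(flt$graph),
         vein_lengths = edge_length_distribution(flt$graph))
  })
  out <- list(mesh = mesh, forcing = f, solution = solution, pregraph = pregraph,
              terminals = terminals, filter_result = flt$result,
              filtered = flt$graph, metrics = metrics, config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_mesh(run$mesh, p("mesh.txt"))
  write_solution(run$solution, run$mesh, p("continuous"))
  write_graph_tsv(run$pregraph, p("pregraph"))
  write_graphml(run$pregraph, p("pregraph.graphml"))
  write_terminals(run$terminals, run$pregraph, p("terminals.tsv"))
  write_graph_tsv(run$filtered, p("filtered"))
  write_graphml(run$filtered, p("filtered.graphml"))
  es <- run$filter_result$energy_split
  jsonlite::write_json(list(operating_pct = es$operating_pct,
                            infrastructure_pct = es$infrastructure_pct,
                            total = es$total,
                            iterations = run$filter_result$iterations,
                            converged = run$filter_result$converged),
                       p("filter_energy.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(w_hat = run$metrics$w_hat$w_hat,
                            q = run$metrics$w_hat$q,
                            total_length = run$metrics$length,
                            n_veins = length(run$metrics$vein_lengths)),
                       p("metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(length = run$metrics$vein_lengths),
                   p("vein_lengths.csv"), row.names = FALSE)
  manifest <- list(
    config = config_to_list(run$config),
    config_hash = config_hash(run$config),
    package_version = as.character(utils::packageVersion("routenet")),
    r_version = R.version.string,
    continuous_converged = run$solution$converged,
    continuous_iterations = run$solution$iterations,
    filter_converged = run$filter_result$converged)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$forcing <- lapply(cfg$forcing$regions, function(r) unclass(r))
  cfg
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config_to_list(config))), collapse = "\n")
  # small stable polynomial hash; enough to identify a configuration
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] structure; forcing regions are
#' listed under `forcing` with their shape, sign, rate and geometry fields.
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- lapply(y$forcing, function(r)
    do.call(forcing_region, r))
  y$forcing <- NULL
  do.call(pipeline_config, c(list(forcing = forcing_spec(regions)), y))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- config_to_list(config)
  names(cfg)[names(cfg) == "forcing"] <- "forcing"
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Built-in study fixtures
#'
#' Named routing problems and inputs emulating the study conditions of the
#' pipeline:
#' * `"two-rectangles"`: one source rectangle on the left, one sink rectangle
#'   on the right;
#' * `"one-sink-four-sources"`: four small source rectangles around a central
#'   sink rectangle;
#' * `"disk-annulus"`: a central disk source
#'   \eqn{(x-0.5)^2 + (y-0.5)^2 \le 0.01} and an annular sink
#'   \eqn{0.01 < (x-0.5)^2+(y-0.5)^2 \le 0.45} -- the venation-network
#'   layout;
#' * `"rect-family"`: a list of configurations with source/sink rectangles
#'   placed at several positions along the domain;
#' * `"uniform-mu0"`, `"parabola-mu0"`, `"delta-mu0"`: the disk-annulus
#'   problem under the three initial-conductivity families;
#' * `"synthetic-skeleton"`: a deterministic synthetic loopy skeleton image
#'   (list with `image`, a 0/1 intensity matrix) for image-input tests.
#'
#' @param name fixture name.
#' @param seed integer seed stored in the configuration.
#' @return a `pipeline_config`, a list of them (`"rect-family"`), or a list
#'   with an `image` matrix (`"synthetic-skeleton"`).
#' @export
generate_fixture <- function(name, seed = 1L) {
  fixtures <- c("two-rectangles", "one-sink-four-sources", "disk-annulus",
                "rect-family", "uniform-mu0", "parabola-mu0", "delta-mu0",
                "synthetic-skeleton")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  rect <- function(sign, xmin, xmax, ymin, ymax)
    forcing_region("rectangle", sign = sign, xmin = xmin, xmax = xmax,
                   ymin = ymin, ymax = ymax)
  disk_annulus <- forcing_spec(list(
    forcing_region("disk", sign = +1, cx = 0.5, cy = 0.5, r = 0.1),
    forcing_region("annulus", sign = -1, cx = 0.5, cy = 0.5,
                   r_in = 0.1, r_out = sqrt(0.45))))
  switch(name,
    "two-rectangles" = pipeline_config(
      forcing_spec(list(rect(+1, 0.10, 0.20, 0.40, 0.60),
                        rect(-1, 0.80, 0.90, 0.40, 0.60))),
      seed = seed),
    "one-sink-four-sources" = pipeline_config(
      forcing_spec(list(rect(-1, 0.45, 0.55, 0.45, 0.55),
                        rect(+1, 0.05, 0.15, 0.05, 0.15),
                        rect(+1, 0.85, 0.95, 0.05, 0.15),
                        rect(+1, 0.05, 0.15, 0.85, 0.95),
                        rect(+1, 0.85, 0.95, 0.85, 0.95))),
      seed = seed),
    "disk-annulus" = pipeline_config(disk_annulus, seed = seed),
    "rect-family" = {
      placements <- list(c(0.1, 0.9), c(0.1, 0.5), c(0.5, 0.9), c(0.3, 0.7))
      lapply(placements, function(pq)
        pipeline_config(
          forcing_spec(list(rect(+1, pq[1] - 0.05, pq[1] + 0.05, 0.4, 0.6),
                            rect(-1, pq[2] - 0.05, pq[2] + 0.05, 0.4, 0.6))),
          seed = seed))
    },
    "uniform-mu0" = pipeline_config(disk_annulus, seed = seed,
                                    continuous = list(mu0 = "uniform")),
    "parabola-mu0" = pipeline_config(disk_annulus, seed = seed,
                                     continuous = list(mu0 = "parabola")),
    "delta-mu0" = pipeline_config(disk_annulus, seed = seed,
                                  continuous = list(mu0 = "delta")),
    "synthetic-skeleton" = list(image = skeleton_image(seed = seed)))
}

# Deterministic synthetic loopy skeleton: a rectangle circuit with a chord,
# drawn 1 pixel wide on a dark background.
skeleton_image <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  img <- matrix(0, n, n)
  lo <- round(n * 0.2); hi <- round(n * 0.8); mid <- round(n * 0.5)
  img[lo, lo:hi] <- 1; img[hi, lo:hi] <- 1
  img[lo:hi, lo] <- 1; img[lo:hi, hi] <- 1
  img[lo:hi, mid] <- 1
  img
}
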