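#' Run the full signed-network analysis pipeline
#'
#' Loads (or builds) a signed network, computes the link-clustering
#' coefficient table and the common-neighbor profile, runs the triad census
#' with the sign-shuffle null, extracts positive-link modules at the
#' density-maximising cutoff, builds the module map, and writes every result
#' as TSV plus a machine-readable JSON run manifest. Given the same
#' configuration and seed the outputs are identical.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{net}{path to a signed edge-list TSV (exclusive with `expr`)}
#'     \item{expr}{path to an expression matrix TSV; a coexpression network
#'       is built with `pos_threshold` / `neg_threshold`}
#'     \item{out_dir}{output directory (created if missing)}
#'     \item{pos_threshold, neg_threshold}{correlation thresholds
#'       (defaults 0.9 / -0.9)}
#'     \item{denominator}{coefficient convention (default "min_total")}
#'     \item{n_shuffles}{sign shuffles for the triad null (default 1000)}
#'     \item{seed}{integer seed (default 1)}
#'     \item{min_genes}{minimum module size (default 3)}
#'     \item{tie_rule}{cutoff tie rule (default "stringent")}
#'   }
#' @param quiet suppress progress messages (default FALSE)
#' @return invisibly, a list with the in-memory results (`network`, `coeffs`,
#'   `cnb`, `triads`, `partition`, `map`) and `manifest`
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  defaults <- list(pos_threshold = 0.9, neg_threshold = -0.9,
                   denominator = "min_total", n_shuffles = 1000L,
                   seed = 1L, min_genes = 3L, tie_rule = "stringent")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$expr)) {
      if (!file.exists(config$expr)) stop("expression file not found: ", config$expr)
      say("stage input: building coexpression network from ", config$expr)
      expr <- read_expression_matrix(config$expr)
      net <- build_cen(expr, config$pos_threshold, config$neg_threshold)
    } else if (!is.null(config$net)) {
      if (!file.exists(config$net)) stop("network file not found: ", config$net)
      say("stage input: reading signed network from ", config$net)
      net <- read_signed_edge_list(config$net)
    } else {
      stop("config needs either $net or $expr")
    }

    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outp <- function(f) file.path(config$out_dir, f)
    write_signed_edge_list(net, outp("network.tsv"))

    stage <- "coefficients"
    say("stage coefficients: ", nrow(net$edges), " edges")
    coeffs <- link_clustering_coefficients(net, config$denominator)
    utils::write.table(as.data.frame(coeffs), outp("coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "cnb"
    cnb <- cnb_profile(net, coeffs)
    utils::write.table(cnb$profile, outp("cnb_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("cor_med_PLC_vs_HLC\t%s\t%s",
                         format(cnb$cor_PLC), format(cnb$p_PLC)),
                 sprintf("cor_med_HLC_vs_HLC\t%s\t%s",
                         format(cnb$cor_HLC), format(cnb$p_HLC))),
               outp("cnb_correlations.tsv"))

    stage <- "triads"
    say("stage triads: ", config$n_shuffles, " shuffles, seed ", config$seed)
    tc <- triad_enrichment(net, n_shuffles = config$n_shuffles,
                           seed = config$seed)
    utils::write.table(
      data.frame(type = names(tc$counts), pattern = unname(tc$patterns),
                 observed = unname(tc$counts),
                 null_mean = unname(tc$null_mean),
                 null_sd = unname(tc$null_sd), fold = unname(tc$fold),
                 p_over = unname(tc$p_over), p_under = unname(tc$p_under)),
      outp("triads.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "cluster"
    part <- NULL
    if (any(net$edges$sign > 0)) {
      part <- extract_modules(net, sign = 1, min_genes = config$min_genes,
                              tie_rule = config$tie_rule)
      utils::write.table(part$sweep, outp("sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mod_df <- if (length(part$modules)) {
        data.frame(module_id = rep(names(part$modules),
                                   lengths(part$modules)),
                   gene = unlist(part$modules, use.names = FALSE))
      } else data.frame(module_id = character(), gene = character())
      utils::write.table(mod_df, outp("modules.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "module_map"
    map <- NULL
    if (!is.null(part) && length(part$modules) >= 1L) {
      map <- module_map(net, part$modules)
      utils::write.table(map$nodes, outp("module_map_nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(map$edges, outp("module_map_edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    manifest <- list(
      package = "siglinc",
      version = as.character(utils::packageVersion("siglinc")),
      config = config[order(names(config))],
      n_nodes = length(net$nodes), n_edges = nrow(net$edges),
      n_positive = sum(net$edges$sign > 0),
      n_negative = sum(net$edges$sign < 0),
      n_modules = if (is.null(part)) 0L else length(part$modules),
      cutoff = if (is.null(part)) NULL else part$cutoff,
      partition_density = if (is.null(part)) NULL else part$D)
    jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(network = net, coeffs = coeffs, cnb = cnb, triads = tc,
         partition = part, map = map, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("pipeline complete: ", config$out_dir)
  invisible(result)
}
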