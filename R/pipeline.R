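#' Read and validate a pipeline configuration
#'
#' YAML with paths (\code{reference}, \code{fasta}, \code{meta},
#' \code{motifs}, \code{out}), optional exclusion-policy overrides
#' (\code{excluded_points}, \code{conditional_ranges}), coding-region
#' bounds (\code{coding_start}, \code{coding_end}), clock rates
#' (\code{clock_complete}, \code{clock_coding}), \code{target_regions},
#' origin-rule settings (\code{origin_rule}, \code{majority_threshold}),
#' \code{root_variants} (space-separated labels of the founder haplotype,
#' default none = the reference), \code{exact_cap} and \code{seed}.
#' Defaults are the published values.
#'
#' @param path YAML config path
#' @return validated config list
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg, dir = dirname(path))
}

#' @rdname readPipelineConfig
#' @param cfg config list
#' @param dir base directory for relative paths
#' @export
validatePipelineConfig <- function(cfg, dir = ".") {
  defaults <- list(coding_start = 577L, coding_end = 16023L,
                   clock_complete = 3624, clock_coding = 4610,
                   target_regions = "Siberia", origin_rule = "unanimity",
                   majority_threshold = 0.75, root_variants = "",
                   exact_cap = 12L, seed = 1L,
                   excluded_points = 16519L,
                   conditional_ranges = list(c(16180L, 16193L),
                                             c(303L, 315L),
                                             c(522L, 524L),
                                             c(573L, 576L)))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("reference", "fasta", "meta", "motifs", "out")) {
    if (is.null(cfg[[nm]])) stop("config is missing required path: ", nm)
    if (nm != "out" && !file.exists(cfg[[nm]])) {
      rel <- file.path(dir, cfg[[nm]])
      if (!file.exists(rel))
        stop("config path does not exist: ", nm, " = ", cfg[[nm]])
      cfg[[nm]] <- rel
    }
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Reads reference, samples and motifs; scores variants; applies the
#' exclusion policy; builds the complete-mask maximum-parsimony tree;
#' assigns haplogroups; dates all named subclades under both clocks
#' (the coding clock on the coding-masked re-projection); finds
#' target-region-specific subclades; classifies their origin by nesting;
#' and writes the deterministic report bundle.
#'
#' @param cfg config list (from \code{\link{readPipelineConfig}}) or a
#'   YAML path
#' @param quiet suppress stage messages
#' @return invisibly, a list with profiles, tree, calls, dating,
#'   regionSpecific, originSummary and the written paths
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  cfg <- validatePipelineConfig(cfg)
  say <- function(...) if (!quiet) message("[mitorho] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, " (", format(round(difftime(Sys.time(), t0,
                                          units = "secs"), 2)), ")")
    out
  }

  ref <- stage("load_reference", loadReference(cfg$reference))
  inp <- stage("read_samples", readSamples(cfg$fasta, cfg$meta))
  motifs <- stage("read_motifs", readMotifTable(cfg$motifs, ref))
  policy <- exclusionPolicy(
    excludedPoints = as.integer(cfg$excluded_points),
    conditionalRanges = do.call(rbind, cfg$conditional_ranges))

  profiles <- stage("call_variants", {
    lapply(seq_along(inp$sequences), function(i)
      callVariants(inp$sequences[[i]], ref,
                   sampleId = names(inp$sequences)[i],
                   population = inp$samples$population[i],
                   regionClass = inp$samples$region_class[i]))
  })
  profiles <- stage("apply_exclusion_filter",
                    lapply(profiles, applyExclusionFilter,
                           policy = policy))

  rootLabels <- strsplit(trimws(cfg$root_variants), "\\s+")[[1]]
  rootLabels <- rootLabels[nzchar(rootLabels)]
  rootProf <- haplotypeProfile("(root)",
                               if (length(rootLabels))
                                 parseVariantLabel(rootLabels, ref)
                               else emptyVariants())
  tree <- stage("build_mp_tree",
                buildMPTree(profiles, rootProf,
                            exactCap = as.integer(cfg$exact_cap)))
  calls <- stage("assign_haplogroup", assignHaplogroups(tree, motifs))
  clocks <- list(
    clock("complete", yearsPerSubstitution = cfg$clock_complete),
    clock("coding", yearsPerSubstitution = cfg$clock_coding))
  dating <- stage("date_all_subclades",
                  dateAllSubclades(tree, motifs, clocks, calls = calls,
                                   exactCap = as.integer(cfg$exact_cap)))
  regionSpecific <- stage("find_region_specific_clades",
                          findRegionSpecificClades(tree,
                                                   cfg$target_regions))
  originSummary <- stage("classify_origins", {
    rs <- regionSpecific$clades
    if (nrow(rs)) {
      oc <- do.call(rbind, lapply(seq_len(nrow(rs)), function(i)
        classifyOriginByNesting(tree, rs$node[i], cfg$target_regions,
                                rule = cfg$origin_rule,
                                majorityThreshold =
                                  cfg$majority_threshold)))
      callsDf <- data.frame(clade = paste0("node", rs$node),
                            origin = oc$origin, n = rs$n_leaves,
                            samples = rs$leaves,
                            evidence = oc$evidence,
                            stringsAsFactors = FALSE)
    } else {
      callsDf <- data.frame(clade = character(), origin = character(),
                            n = integer(), samples = character(),
                            evidence = character(),
                            stringsAsFactors = FALSE)
    }
    summarizeOrigins(callsDf, regionSpecific)
  })
  paths <- stage("write_outputs",
                 writeOutputs(profiles, list(complete = tree), dating,
                              calls, regionSpecific, originSummary,
                              cfg$out))
  invisible(list(profiles = profiles, tree = tree, calls = calls,
                 dating = dating, regionSpecific = regionSpecific,
                 originSummary = originSummary, paths = paths))
}
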