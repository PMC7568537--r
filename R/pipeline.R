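# End-to-end orchestration: data in (simulated, VCF or BEAGLE), filters,
# structure, differentiation, diversity, migration, and the
# diversity-vs-cave-length regression, with every table written as TSV.

#' Pipeline configuration
#'
#' Exactly one input source must be given: `sim` (an
#' [island_model_config()], optionally with `reads`), or `vcf` +
#' `popmap`, or `beagle` + `popmap`.
#'
#' @param sim Optional [island_model_config()].
#' @param reads Optional [read_observation_config()] (simulated input
#'   only); when present the hard-call track is re-called from the
#'   simulated reads and a genotype-likelihood track is analyzed too.
#' @param vcf,beagle,popmap Optional input file paths.
#' @param hard_filters A [hard_filter_params()].
#' @param gl_filters A [gl_filter_params()].
#' @param min_maf IBS minor-allele-frequency floor.
#' @param linkage Clustering linkage.
#' @param k_range Candidate K values for BIC selection and admixture.
#' @param total_positions Interrogated-positions denominator for pi
#'   (default: sites in the input).
#' @param mu Mutation rate for Ne.
#' @param covariates Optional data frame `population`, `length_m` (and
#'   optionally `species`) enabling the pi-vs-length regression.
#' @param out_dir Output directory for TSV/Newick reports (`NULL` for
#'   none).
#' @param seed Integer seed for all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, reads = NULL, vcf = NULL,
                            beagle = NULL, popmap = NULL,
                            hard_filters = hard_filter_params(),
                            gl_filters = gl_filter_params(),
                            min_maf = 0.01, linkage = "average",
                            k_range = 1:8, total_positions = NULL,
                            mu = 2.8e-9, covariates = NULL,
                            out_dir = NULL, seed = 42) {
  sources <- c(sim = !is.null(sim), vcf = !is.null(vcf), beagle = !is.null(beagle))
  if (sum(sources) != 1L) {
    stop("exactly one input source (sim, vcf, beagle) must be given", call. = FALSE)
  }
  if ((!is.null(vcf) || !is.null(beagle)) && is.null(popmap)) {
    stop("file input requires a `popmap` path", call. = FALSE)
  }
  for (f in c(vcf, beagle, popmap)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  structure(list(sim = sim, reads = reads, vcf = vcf, beagle = beagle,
                 popmap = popmap, hard_filters = hard_filters,
                 gl_filters = gl_filters, min_maf = min_maf,
                 linkage = linkage, k_range = k_range,
                 total_positions = total_positions, mu = mu,
                 covariates = covariates, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: ingest or simulate; hard-call and (when likelihoods exist)
#' genotype-likelihood filtering; IBS distances, hierarchical clustering,
#' MDS, BIC-based K selection and admixture; pairwise differentiation;
#' per-population diversity and Ne; island-model migration rates; and,
#' when cave-length covariates are supplied, the pi-vs-log10(length)
#' regression. Fully deterministic given the configuration's seeds. When
#' `out_dir` is set, each completed stage's tables are written before the
#' next begins, so a failing stage leaves earlier outputs on disk.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `filter_report`, `gl_filter_report`,
#'   `distances`, `tree`, `mds`, `k_selection`, `admixture` (list by K),
#'   `fst_table`, `diversity_table`, `migration`, `regression`, `log`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  out <- list(log = character(0))
  say <- function(...) {
    line <- sprintf(...)
    message("[cavepop] ", line)
    out$log <<- c(out$log, line)
  }
  odir <- config$out_dir
  if (!is.null(odir) && !dir.exists(odir)) dir.create(odir, recursive = TRUE)
  emit <- function(obj, name) {
    if (is.null(odir)) return(invisible(NULL))
    write.table(obj, file.path(odir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  stage <- "input"
  res <- try({
    gl <- NULL
    if (!is.null(config$sim)) {
      ds <- simulate_island_model(config$sim)
      pm <- ds$population_map
      if (!is.null(config$reads)) {
        reads <- simulate_reads(ds, config$reads)
        gl <- reads$gl
        geno <- call_genotypes(gl, depth = reads$depth)
      } else {
        geno <- ds$genotypes
      }
      say("simulated %d demes x %d sites (m = %g, seed %d)",
          config$sim$n_demes, config$sim$n_sites,
          config$sim$migration_rate, config$sim$seed)
    } else if (!is.null(config$vcf)) {
      geno <- read_vcf(config$vcf)
      pm <- read_popmap(config$popmap)
      say("read %d samples x %d sites from %s", n_samples(geno),
          n_sites(geno), config$vcf)
    } else {
      gl <- read_beagle_gl(config$beagle)
      pm <- read_popmap(config$popmap)
      geno <- call_genotypes(gl)
      say("read GLs for %d samples x %d sites from %s", n_samples(gl),
          n_sites(gl), config$beagle)
    }
    align_popmap(geno, pm)                     # fail early on unlabelled samples
    total_positions <- config$total_positions %||% n_sites(geno)

    stage <- "filter"
    hf <- config$hard_filters
    if (is.null(geno$depth) && hf$min_genotype_depth > 0L) {
      hf$min_genotype_depth <- 0L
      say("no depth in input: genotype-depth rule disabled")
    }
    filt <- filter_hard_calls(geno, hf)
    geno_f <- filt$matrix
    out$filter_report <- filt$report
    say("hard filters: %d -> %d sites", filt$report$n_input, filt$report$n_retained)
    emit(filt$report$rules, "filter_report.tsv")
    if (!is.null(gl)) {
      glf <- filter_gl_sites(gl, config$gl_filters)
      out$gl_filter_report <- glf$report
      gl_f <- glf$tensor
      say("GL filters: %d -> %d sites", glf$report$n_input, glf$report$n_retained)
      emit(glf$report$rules, "gl_filter_report.tsv")
    }

    stage <- "structure"
    D <- ibs_distance_matrix(geno_f, min_maf = config$min_maf,
                             seed = config$seed)
    out$distances <- D
    emit(data.frame(sample = rownames(D$d), D$d, check.names = FALSE),
         "ibs_distances.tsv")
    out$tree <- hierarchical_cluster(D, linkage = config$linkage)
    if (!is.null(odir)) writeLines(out$tree$newick, file.path(odir, "tree.nwk"))
    out$mds <- classical_mds(D)
    emit(data.frame(sample = D$samples, out$mds$coords), "mds_coords.tsv")
    out$k_selection <- select_k_bic(out$mds$coords, k_range = config$k_range,
                                    seed = config$seed)
    emit(out$k_selection$table, "bic_table.tsv")
    say("selected K = %d by BIC", out$k_selection$selected_k)
    adm_input <- if (!is.null(gl)) gl_f else geno_f
    ks <- config$k_range[config$k_range >= 2 & config$k_range <= n_samples(geno_f)]
    out$admixture <- lapply(setNames(ks, paste0("K", ks)), function(k) {
      r <- admixture_em(adm_input, K = k, seed = config$seed)
      emit(data.frame(sample = r$samples, r$Q), sprintf("admixture_Q_K%d.tsv", k))
      r
    })

    stage <- "differentiation"
    out$fst_table <- pairwise_stats(geno_f, pm)
    emit(out$fst_table, "fst_table.tsv")
    say("differentiation over %d pairs", nrow(out$fst_table))

    stage <- "diversity"
    pops <- sort(unique(pm$population[pm$sample %in% geno_f$samples]))
    div <- lapply(pops, function(p) {
      hard <- pi_hard(geno_f, pm, p, total_positions = total_positions,
                      mu = config$mu)
      row <- data.frame(population = p, method = "hard-call",
                        pi_per_site = hard$pi_per_site, S = hard$S,
                        total_positions = hard$total_positions, ne = hard$ne,
                        stringsAsFactors = FALSE)
      if (!is.null(gl)) {
        glr <- pi_gl(gl_f, pm, p, total_positions = total_positions,
                     mu = config$mu)
        row <- rbind(row, data.frame(population = p, method = "GL-SFS",
                                     pi_per_site = glr$pi_per_site, S = glr$S,
                                     total_positions = glr$total_positions,
                                     ne = glr$ne, stringsAsFactors = FALSE))
      }
      row
    })
    out$diversity_table <- do.call(rbind, div)
    emit(out$diversity_table, "diversity_table.tsv")
    say("diversity over %d populations (mu = %g; Ne order-of-magnitude only)",
        length(pops), config$mu)

    stage <- "migration"
    ne_method <- if (!is.null(gl)) "GL-SFS" else "hard-call"
    dtab <- out$diversity_table[out$diversity_table$method == ne_method, ]
    ne_by_pop <- setNames(dtab$ne, dtab$population)
    out$migration <- migration_report(out$fst_table, ne_by_pop,
                                      fst_column = "wc_fst")
    emit(out$migration, "migration_table.tsv")

    stage <- "regression"
    if (!is.null(config$covariates)) {
      cov <- config$covariates
      pi_vec <- dtab$pi_per_site[match(cov$population, dtab$population)]
      out$regression <- pi_length_regression(pi_vec, cov$length_m,
                                             species = cov$species)
      emit(data.frame(term = names(out$regression$coefficients),
                      estimate = out$regression$coefficients),
           "regression_coefficients.tsv")
      say("pi ~ log10(length): slope %.3g, R^2 %.3f",
          out$regression$slope, out$regression$r_squared)
    } else {
      say("no covariate table: regression stage skipped")
    }
    TRUE
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  }
  if (!is.null(odir)) writeLines(out$log, file.path(odir, "run_log.txt"))
  class(out) <- "pipeline_result"
  out
}

#' Diversity-vs-cave-length regression
#'
#' Ordinary least squares of per-population nucleotide diversity on
#' log10(cave length in m), with an optional additive species term.
#'
#' @param pi Per-population nucleotide diversity values.
#' @param length_m Cave lengths in meters (positive).
#' @param species Optional species labels for an additive term.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (slope
#'   t-test), `n`, `coefficients`, `predictor`.
#' @export
pi_length_regression <- function(pi, length_m, species = NULL) {
  if (length(pi) < 3) stop("need at least 3 populations", call. = FALSE)
  if (any(length_m <= 0)) stop("cave lengths must be positive", call. = FALSE)
  dat <- data.frame(pi = pi, loglen = log10(length_m))
  form <- pi ~ loglen
  if (!is.null(species) && length(unique(species)) > 1) {
    dat$species <- factor(species)
    form <- pi ~ loglen + species
  }
  fit <- lm(form, data = dat)
  sm <- summary(fit)
  list(slope = unname(coef(fit)["loglen"]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["loglen", "Pr(>|t|)"],
       n = nrow(dat), coefficients = coef(fit),
       predictor = paste(deparse(form), collapse = ""))
}

#' Pairwise migration-rate table
#'
#' For every population pair in an F_ST table, inverts
#' `E(FST) = 1 / (1 + 4 Ne m)` to the scaled migrant number
#' `M = 1/FST - 1` and, with the mean of the pair's effective sizes,
#' the per-generation migration rate `m = M / (4 Ne)`.
#'
#' @param fst_tab Data frame with columns `pop_a`, `pop_b` and the F_ST
#'   column named by `fst_column`.
#' @param ne_by_pop Named numeric vector of per-population Ne.
#' @param fst_column Which column holds the F_ST to invert (default
#'   `"wc_fst"`).
#' @return Data frame `pop_a`, `pop_b`, `fst`, `M`, `ne_used`, `m`, with
#'   attributes `mean_M` and `max_m`; pairs lacking an Ne are dropped
#'   with a warning.
#' @export
migration_report <- function(fst_tab, ne_by_pop, fst_column = "wc_fst") {
  if (!fst_column %in% names(fst_tab)) {
    stop("no column `", fst_column, "` in `fst_tab`", call. = FALSE)
  }
  have_ne <- fst_tab$pop_a %in% names(ne_by_pop) &
    fst_tab$pop_b %in% names(ne_by_pop)
  if (any(!have_ne)) {
    warning("skipping pairs without Ne: ",
            paste(fst_tab$pop_a[!have_ne], fst_tab$pop_b[!have_ne],
                  sep = "-", collapse = ", "))
    fst_tab <- fst_tab[have_ne, , drop = FALSE]
  }
  fst <- fst_tab[[fst_column]]
  ne <- (ne_by_pop[fst_tab$pop_a] + ne_by_pop[fst_tab$pop_b]) / 2
  M <- ifelse(fst > 0, 1 / fst - 1, NA_real_)
  out <- data.frame(pop_a = fst_tab$pop_a, pop_b = fst_tab$pop_b,
                    fst = fst, M = M, ne_used = unname(ne),
                    m = M / (4 * unname(ne)), stringsAsFactors = FALSE)
  attr(out, "mean_M") <- mean(M, na.rm = TRUE)
  attr(out, "max_m") <- max(out$m, na.rm = TRUE)
  out
}
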