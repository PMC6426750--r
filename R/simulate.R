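#' Genotype simulation configuration
#'
#' @param n number of diploid samples.
#' @param m number of biallelic markers.
#' @param maf_range uniform range for the minor allele frequency.
#' @param ld_rho adjacent-marker haplotype copying probability in `[0, 1)`;
#'   0 gives independent markers, values near 1 give long-range LD.
#' @param seed integer seed.
#' @return A `genotype_sim_config` list.
#' @export
genotype_sim_config <- function(n, m, maf_range = c(0.05, 0.5),
                                ld_rho = 0, seed = 1L) {
  stopifnot(n >= 1, m >= 1,
            length(maf_range) == 2,
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1)
  structure(list(n = as.integer(n), m = as.integer(m),
                 maf_range = as.numeric(maf_range),
                 ld_rho = as.numeric(ld_rho), seed = as.integer(seed)),
            class = "genotype_sim_config")
}

#' Simulate biallelic genotypes with tunable LD
#'
#' Generates `2n` haplotypes marker by marker as a first-order copying
#' chain: the allele at marker `j` copies the allele at marker `j - 1`
#' with probability `ld_rho`, otherwise it is drawn fresh at that marker's
#' allele frequency. Diploid dosages are sums of two independent
#' haplotypes, so Hardy-Weinberg proportions hold marginally. Minor allele
#' frequencies are uniform on `maf_range`; the orientation of allele A is
#' randomized per marker.
#'
#' @param cfg a [genotype_sim_config()].
#' @return A complete `genotype_matrix`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "genotype_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n; m <- cfg$m
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    flip <- runif(m) < 0.5
    p <- ifelse(flip, 1 - maf, maf)   # frequency of allele A
    nh <- 2L * n
    h <- matrix(0L, nh, m)
    h[, 1] <- rbinom(nh, 1L, p[1])
    if (m > 1) {
      for (j in 2:m) {
        copy <- runif(nh) < cfg$ld_rho
        fresh <- rbinom(nh, 1L, p[j])
        h[, j] <- ifelse(copy, h[, j - 1], fresh)
      }
    }
    d <- h[seq_len(n), , drop = FALSE] + h[n + seq_len(n), , drop = FALSE]
    genotype_matrix(d,
                    sample_ids = sprintf("ind_%04d", seq_len(n)),
                    marker_ids = sprintf("snp_%05d", seq_len(m)))
  })
}

#' Trait architecture specification
#'
#' Architectures mirror the taxonomy of real breeding traits: one causal
#' variant of large effect (`single_qtn`), a normal-mixture architecture
#' whose effect-size classes mirror the BayesR variance classes
#' (`mixture`), additive-plus-dominance action (`dominance`), and a
#' liability-threshold case-control trait (`liability_case_control`).
#'
#' @param kind one of `"single_qtn"`, `"mixture"`, `"dominance"`,
#'   `"liability_case_control"`.
#' @param h2_target target heritability in `[0, 1]` (variance ratio on the
#'   realized cohort).
#' @param class_props length-4 proportions of markers falling in the four
#'   effect-variance classes `(0, 1e-4, 1e-3, 1e-2) * sigma_g2`
#'   (mixture/dominance/liability kinds). Must sum to 1.
#' @param n_qtn number of causal markers for `single_qtn` (fixed at 1).
#' @param dominance_ratio ratio of dominance to additive genetic variance
#'   (dominance kind).
#' @param prevalence case fraction for the liability kind.
#' @param min_maf minimum MAF required of a drawn QTN.
#' @return A `trait_architecture` list.
#' @export
trait_architecture <- function(kind = c("single_qtn", "mixture", "dominance",
                                        "liability_case_control"),
                               h2_target = 0.5,
                               class_props = c(0.95, 0.03, 0.015, 0.005),
                               n_qtn = 1L, dominance_ratio = 0.25,
                               prevalence = 0.5, min_maf = 0.05) {
  kind <- match.arg(kind)
  stopifnot(h2_target >= 0, h2_target <= 1,
            length(class_props) == 4, all(class_props >= 0))
  if (abs(sum(class_props) - 1) > 1e-8)
    stop_gs("class_props must sum to 1")
  structure(list(kind = kind, h2_target = h2_target,
                 class_props = class_props, n_qtn = as.integer(n_qtn),
                 dominance_ratio = dominance_ratio,
                 prevalence = prevalence, min_maf = min_maf),
            class = "trait_architecture")
}

#' Simulate a quantitative trait on given genotypes
#'
#' Draws causal markers and effects per the architecture, builds genetic
#' values from centered dosages (plus dominance deviations for the
#' dominance kind), and adds a normal residual that is orthogonalized
#' against the genetic values and rescaled so the realized variance ratio
#' `Var(genetic)/Var(phenotype)` equals `h2_target` exactly on the
#' simulated cohort (residual exactly zero when `h2_target = 1`). The
#' liability kind thresholds the latent value at the quantile giving the
#' configured prevalence.
#'
#' @param g a complete `genotype_matrix`.
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @return A `simulated_trait`: `phenotype`, `true_genetic_values`,
#'   `qtn_indices`, `qtn_effects`, `realized_h2`, `h2_target`.
#' @export
simulate_trait <- function(g, arch, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(arch, "trait_architecture"))
  d <- g$dosages
  if (anyNA(d)) stop_gs("missing genotype calls; run mean_impute() first")
  n <- nrow(d); m <- ncol(d)
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  withr::with_seed(seed, {
    if (arch$kind == "single_qtn") {
      if (m < 1) stop_gs("no markers")
      qtn <- NA_integer_
      for (attempt in seq_len(100)) {
        cand <- sample.int(m, 1)
        if (maf[cand] >= arch$min_maf && var(d[, cand]) > 0) { qtn <- cand; break }
      }
      if (is.na(qtn)) stop_gs("could not draw a polymorphic QTN in 100 attempts")
      effects <- setNames(1, marker_ids(g)[qtn])  # scale-free after h2 normalization
      gval <- (d[, qtn] - 2 * p[qtn]) * effects
      qtn_idx <- qtn
    } else {
      scalers <- c(0, 1e-4, 1e-3, 1e-2)
      cls <- sample.int(4, m, replace = TRUE, prob = arch$class_props)
      beta <- rnorm(m, 0, sqrt(scalers[cls]))
      beta[maf == 0] <- 0  # monomorphic markers carry no signal
      causal <- which(beta != 0)
      if (length(causal) == 0 || sum(beta^2) == 0)
        stop_gs("architecture has zero genetic variance (no non-null effect classes drawn)")
      Wc <- sweep(d, 2, 2 * p)
      gval <- as.numeric(Wc %*% beta)
      if (arch$kind == "dominance" && arch$dominance_ratio > 0) {
        wd <- .dominance_codes(d, p)
        delta <- rnorm(m, 0, sqrt(scalers[cls]))
        dval <- as.numeric(wd %*% delta)
        if (var(dval) > 0) {
          dval <- dval * sqrt(arch$dominance_ratio * var(gval) /
                                var(dval))
          gval <- gval + dval
        }
      }
      qtn_idx <- causal
      effects <- setNames(beta[causal], marker_ids(g)[causal])
    }
    vg <- var(gval)
    if (vg <= 0) stop_gs("zero genetic variance among simulated values")
    h2 <- arch$h2_target
    if (h2 == 0) stop_gs("h2_target = 0 gives a trait with no genetic signal; not supported")
    if (h2 == 1) {
      eps <- rep(0, n)
    } else {
      eps <- rnorm(n)
      eps <- resid(lm(eps ~ gval))                # orthogonal to the genetic values
      eps <- eps * sqrt(vg * (1 - h2) / h2 / var(eps))
    }
    latent <- gval + eps
    if (arch$kind == "liability_case_control") {
      cut <- quantile(latent, 1 - arch$prevalence)
      pheno <- as.numeric(latent > cut)
    } else {
      pheno <- latent
    }
    structure(list(
      phenotype = setNames(pheno, sample_ids(g)),
      true_genetic_values = setNames(gval, sample_ids(g)),
      qtn_indices = qtn_idx,
      qtn_effects = effects,
      realized_h2 = vg / var(latent),
      h2_target = h2,
      kind = arch$kind
    ), class = "simulated_trait")
  })
}

# Aliloo dominance codes for raw dosage matrix d and frequencies p
.dominance_codes <- function(d, p) {
  q <- 1 - p
  w <- matrix(0, nrow(d), ncol(d))
  for (code in c(0, 1, 2)) {
    val <- switch(as.character(code),
                  "2" = -2 * q^2, "1" = 2 * p * q, "0" = -2 * p^2)
    hit <- d == code
    w[hit] <- rep(val, each = nrow(d))[hit]
  }
  w
}

#' @export
print.simulated_trait <- function(x, ...) {
  cat(sprintf("simulated_trait (%s): n=%d, %d causal markers, realized h2 = %.3f (target %.3f)\n",
              x$kind, length(x$phenotype), length(x$qtn_indices),
              x$realized_h2, x$h2_target))
  invisible(x)
}

#' Marker-density experiment with the causal variant included or excluded
#'
#' For a trait controlled by a single QTN, builds nested marker panels
#' from the non-QTN markers at each requested density. With
#' `include_qtn = TRUE` the QTN is prepended to every panel (a density-1
#' panel is the QTN alone); with `include_qtn = FALSE` the QTN is absent
#' from every panel. Additive GBLUP accuracy is evaluated per panel by the
#' full cross-validation protocol.
#'
#' @param g the `genotype_matrix` the trait was simulated on.
#' @param trait a `simulated_trait` with exactly one QTN.
#' @param sizes strictly increasing total panel sizes.
#' @param include_qtn logical scenario flag.
#' @param plan a [make_cv_plan()].
#' @param seed seed for the nested subsampling of non-QTN markers.
#' @return Data frame: `density`, `scenario`, `mean_r`, `se_r`.
#' @export
qtn_inclusion_experiment <- function(g, trait, sizes, include_qtn, plan,
                                     seed = 1L) {
  stopifnot(inherits(trait, "simulated_trait"))
  if (length(trait$qtn_indices) != 1)
    stop_gs("trait must have exactly one QTN")
  m <- ncol(g$dosages)
  sizes <- as.integer(sizes)
  if (any(sizes < 1) || any(sizes > m)) stop_gs("sizes out of range")
  if (length(sizes) > 1 && any(diff(sizes) <= 0))
    stop_gs("sizes must be strictly increasing")
  qtn <- trait$qtn_indices
  others <- setdiff(seq_len(m), qtn)
  go <- subset_markers(g, others)
  need <- if (include_qtn) sizes - 1L else sizes
  pos_need <- unique(need[need > 0])
  idx_sets <- if (length(pos_need))
    nested_subsample(go, pos_need, seed) else list()
  scenario <- if (include_qtn) "QTN included" else "QTN excluded"
  rows <- lapply(seq_along(sizes), function(i) {
    k <- need[i]
    base_idx <- if (k > 0) others[idx_sets[[as.character(k)]]] else integer(0)
    panel <- if (include_qtn) c(qtn, base_idx) else base_idx
    if (length(panel) == 0) stop_gs("empty marker panel at density ", sizes[i])
    gs_msg(sprintf("QTN experiment: density %d (%s)", sizes[i], scenario))
    acc <- run_cv("gblup_a", subset_markers(g, panel), trait$phenotype, plan,
                  density_label = sizes[i])
    data.frame(density = sizes[i], scenario = scenario,
               mean_r = acc$mean_r, se_r = acc$se_r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the ground truth of a simulated trait
#'
#' Companion tables for parameter-recovery tests: the phenotype table (via
#' [write_phenotypes()]) plus a truth TSV of QTN index, effect and true
#' genetic value per sample.
#'
#' @param trait a `simulated_trait`.
#' @param path output path for the truth TSV.
#' @return `path`, invisibly.
#' @export
write_trait_truth_tsv <- function(trait, path) {
  stopifnot(inherits(trait, "simulated_trait"))
  tab <- data.frame(sample_id = names(trait$phenotype),
                    phenotype = as.numeric(trait$phenotype),
                    true_genetic_value = as.numeric(trait$true_genetic_values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
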