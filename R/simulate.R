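# Synthetic multi-omics cohort generator with planted ground truth. The
# generator emulates the study conditions the pipeline is built for: a small
# tumor/normal cohort (20 + 10 samples) profiled on four layers, with driver
# genes whose expression change is explained by concordant copy-number,
# methylation and opposing-miRNA events, co-expression modules driven by
# regulator genes through a shared two-state activity profile, passenger
# candidates with weak but concordant secondary alterations accumulating
# inside modules, and survival times tied to one prognostic gene.

#' Specification of a synthetic multi-omics cohort
#'
#' Defaults mirror the cohort scale and effect magnitudes of the packaged
#' reference tables: 20 tumors / 10 normals, ~1000 genes, driver expression
#' shifts around 2 log2 units, copy-number log ratios of +/-0.4 in half the
#' tumors, methylation shifts of +/-1.5 and per-miRNA shifts of +/-2.5 (two
#' opposing miRNAs per driver, so the aggregated miRNA effect is ~5, the
#' scale of the packaged table), against gene-level noise of sd 0.5.
#'
#' @param n_tumor,n_normal Cohort sizes (defaults 20 / 10).
#' @param n_genes,n_mirnas Feature counts (defaults 1000 / 150).
#' @param n_modules Planted co-expression modules (default 8).
#' @param module_size_range Inclusive member-count range per module
#'   (default 10-40).
#' @param n_drivers Planted driver genes (default 16); the first
#'   `n_modules` of them regulate one module each.
#' @param driver_pattern Logical matrix (`n_drivers` x 3, columns
#'   `cna`,`me`,`mi`) saying which non-expression layers are planted
#'   concordant per driver; default all three.
#' @param ge_fc_mean,ge_fc_sd Driver expression shift: magnitude
#'   `|N(mean, sd)|`, random sign (default 2, 0.5).
#' @param cna_lr,me_fc,mirna_fc Planted driver effect magnitudes per layer.
#' @param cna_penetrance Fraction of tumors carrying a driver's copy-number
#'   event (default 0.5).
#' @param mirnas_per_driver Opposing miRNAs planted per driver (default 2).
#' @param passenger_fraction Fraction of each module's members planted as
#'   passenger candidates (default 0.3).
#' @param passenger_ge_fc,passenger_cna_lr,passenger_me_fc,passenger_penetrance
#'   Weak-but-eligible passenger effects (defaults 1.0, 0.25, 0.8, 0.35).
#' @param member_ge_fc Expression shift of ordinary module members
#'   (default 1.2), `scattered_ge_fc` of the `n_scattered` (default 40)
#'   differentially expressed genes outside any module (default 1.5).
#' @param state_amplitude,module_coupling Amplitude of the regulator's
#'   two-state tumor activity profile and of its propagation into member
#'   genes (defaults 1.5 / 1.0).
#' @param noise_sd Gene-level noise sd for expression / methylation / miRNA
#'   (default 0.5); `cna_noise_sd` for segmented copy-number ratios
#'   (default 0.05).
#' @param prognostic_hr Hazard ratio per sd of the prognostic gene's tumor
#'   expression (default 3); `followup_window` months of uniform independent
#'   censoring (default 36, giving roughly a third censored).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec and seed.
#' @param scattered_ge_fc,n_scattered,cna_noise_sd,followup_window See above.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumor = 20L, n_normal = 10L, n_genes = 1000L,
                        n_mirnas = 150L, n_modules = 8L,
                        module_size_range = c(10L, 40L), n_drivers = 16L,
                        driver_pattern = NULL,
                        ge_fc_mean = 2, ge_fc_sd = 0.5, cna_lr = 0.4,
                        me_fc = 1.5, mirna_fc = 2.5, cna_penetrance = 0.5,
                        mirnas_per_driver = 2L,
                        passenger_fraction = 0.3, passenger_ge_fc = 1.0,
                        passenger_cna_lr = 0.25, passenger_me_fc = 0.8,
                        passenger_penetrance = 0.35,
                        member_ge_fc = 1.2, scattered_ge_fc = 1.5,
                        n_scattered = 40L,
                        state_amplitude = 1.5, module_coupling = 1.0,
                        noise_sd = 0.5, cna_noise_sd = 0.05,
                        prognostic_hr = 3, followup_window = 36,
                        seed = 42L) {
  if (is.null(driver_pattern))
    driver_pattern <- matrix(TRUE, n_drivers, 3,
                             dimnames = list(NULL, c("cna", "me", "mi")))
  stopifnot(n_drivers <= n_genes, n_modules <= n_drivers,
            cna_penetrance > 0, cna_penetrance <= 1,
            passenger_penetrance > 0, passenger_penetrance <= 1,
            passenger_fraction >= 0, passenger_fraction <= 1,
            n_tumor > 0, n_normal > 0, n_genes > 0, n_mirnas > 0,
            length(module_size_range) == 2L,
            module_size_range[1] <= module_size_range[2],
            nrow(driver_pattern) == n_drivers,
            prognostic_hr > 0, followup_window > 0,
            noise_sd >= 0, cna_noise_sd >= 0)
  need <- n_drivers + n_modules * module_size_range[2] + n_scattered
  if (need > n_genes)
    stop("n_genes too small for the requested drivers, modules and scattered genes")
  if (n_mirnas < n_drivers * mirnas_per_driver)
    stop("n_mirnas too small for the planted opposing regulators")
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic multi-omics cohort with planted truth
#'
#' Draws the four layer matrices, the miRNA target map, the clinical table
#' and the planted-truth record implied by a [cohort_spec()]. Expression of
#' a module member is its planted tumor/normal shift plus the module's
#' regulator-driven two-state activity plus gene noise; drivers receive
#' concordant shifts in their designated layers (copy number shares the
#' expression sign, methylation and targeting miRNAs oppose it); survival
#' times are exponential with hazard `HR^z` in the standardized prognostic
#' expression `z`, censored uniformly and independently. Fully deterministic
#' given the spec and its seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `expression`, `cna`, `methylation`, `mirna`
#'   ([omics_matrix()] objects), `targets` ([target_map()]), `clinical`
#'   (`data.frame`) and `truth` (planted drivers, passengers, module
#'   memberships, regulator pairs, prognostic gene, state matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  tumors <- sprintf("T%02d", seq_len(spec$n_tumor))
  normals <- sprintf("N%02d", seq_len(spec$n_normal))
  samples <- c(tumors, normals)
  group <- setNames(rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal)),
                    samples)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(spec$n_mirnas))

  drivers <- genes[seq_len(spec$n_drivers)]
  regulators <- drivers[seq_len(spec$n_modules)]
  sizes <- sample(seq(spec$module_size_range[1], spec$module_size_range[2]),
                  spec$n_modules, replace = TRUE)
  offset <- spec$n_drivers
  modules <- lapply(seq_len(spec$n_modules), function(m) {
    idx <- offset + seq_len(sizes[m])
    offset <<- offset + sizes[m]
    genes[idx]
  })
  names(modules) <- as.character(seq_len(spec$n_modules))
  scattered <- genes[offset + seq_len(spec$n_scattered)]
  passengers <- unlist(lapply(modules, function(g)
    g[seq_len(floor(spec$passenger_fraction * length(g)))]), use.names = FALSE)

  # planted signs and magnitudes; the prognostic driver is overexpressed
  driver_sign <- c(1, sample(c(-1, 1), spec$n_drivers - 1L, replace = TRUE))
  driver_fc <- driver_sign * abs(rnorm(spec$n_drivers, spec$ge_fc_mean,
                                       spec$ge_fc_sd))
  member_sign <- setNames(sample(c(-1, 1), length(unlist(modules)),
                                 replace = TRUE), unlist(modules))
  scattered_sign <- setNames(sample(c(-1, 1), spec$n_scattered, replace = TRUE),
                             scattered)
  ge_shift <- setNames(numeric(spec$n_genes), genes)
  ge_shift[drivers] <- driver_fc
  ge_shift[names(member_sign)] <- member_sign * spec$member_ge_fc
  ge_shift[passengers] <- member_sign[passengers] * spec$passenger_ge_fc
  ge_shift[scattered] <- scattered_sign * spec$scattered_ge_fc

  # two-state regulator activity per module over tumors (balanced)
  states <- matrix(0L, spec$n_modules, spec$n_tumor,
                   dimnames = list(names(modules), tumors))
  for (m in seq_len(spec$n_modules))
    states[m, sample(spec$n_tumor, floor(spec$n_tumor / 2))] <- 1L

  expr <- matrix(rnorm(spec$n_genes * length(samples), 0, spec$noise_sd),
                 spec$n_genes, dimnames = list(genes, samples))
  expr[, tumors] <- expr[, tumors] + ge_shift
  for (m in seq_len(spec$n_modules)) {
    act <- 2 * states[m, ] - 1
    expr[regulators[m], tumors] <- expr[regulators[m], tumors] +
      spec$state_amplitude * act
    expr[modules[[m]], tumors] <- expr[modules[[m]], tumors] +
      rep(spec$module_coupling * act, each = length(modules[[m]]))
  }

  cna <- matrix(rnorm(spec$n_genes * length(samples), 0, spec$cna_noise_sd),
                spec$n_genes, dimnames = list(genes, samples))
  plant_cna <- function(gene, sgn, lr, penetrance) {
    carriers <- sample(tumors, round(penetrance * spec$n_tumor))
    cna[gene, carriers] <<- cna[gene, carriers] + sgn * lr
  }
  for (d in seq_len(spec$n_drivers))
    if (spec$driver_pattern[d, "cna"])
      plant_cna(drivers[d], driver_sign[d], spec$cna_lr, spec$cna_penetrance)
  for (p in passengers)
    plant_cna(p, member_sign[p], spec$passenger_cna_lr,
              spec$passenger_penetrance)

  meth <- matrix(rnorm(spec$n_genes * length(samples), 0, spec$noise_sd),
                 spec$n_genes, dimnames = list(genes, samples))
  for (d in seq_len(spec$n_drivers))
    if (spec$driver_pattern[d, "me"])
      meth[drivers[d], tumors] <- meth[drivers[d], tumors] -
        driver_sign[d] * spec$me_fc
  meth[passengers, tumors] <- meth[passengers, tumors] -
    member_sign[passengers] * spec$passenger_me_fc

  mirna <- matrix(rnorm(spec$n_mirnas * length(samples), 0, spec$noise_sd),
                  spec$n_mirnas, dimnames = list(mirnas, samples))
  entries <- list()
  mi_idx <- 0L
  for (d in seq_len(spec$n_drivers)) {
    if (!spec$driver_pattern[d, "mi"]) next
    for (k in seq_len(spec$mirnas_per_driver)) {
      mi_idx <- mi_idx + 1L
      mi <- mirnas[mi_idx]
      mirna[mi, tumors] <- mirna[mi, tumors] - driver_sign[d] * spec$mirna_fc
      entries[[mi]] <- c(drivers[d], sample(genes, 3))
    }
  }
  for (mi in setdiff(mirnas, names(entries)))
    entries[[mi]] <- sample(genes, 5)
  targets <- target_map(entries, min_algorithms = 6L)

  prognostic <- drivers[1]
  z <- as.numeric(scale(expr[prognostic, tumors]))
  base_rate <- log(2) / 12                       # 12-month baseline median
  t_event <- rexp(spec$n_tumor, base_rate * spec$prognostic_hr^z)
  t_censor <- runif(spec$n_tumor, 0, spec$followup_window)
  clinical <- data.frame(
    sample_id = tumors,
    time_months = pmin(t_event, t_censor),
    event = as.integer(t_event <= t_censor),
    stringsAsFactors = FALSE)

  truth <- list(
    drivers = data.frame(gene_id = drivers, ge_fc = driver_fc,
                         cna = spec$driver_pattern[, "cna"],
                         me = spec$driver_pattern[, "me"],
                         mi = spec$driver_pattern[, "mi"],
                         stringsAsFactors = FALSE),
    passengers = passengers,
    modules = modules,
    regulator_pairs = data.frame(regulator = regulators,
                                 module = names(modules),
                                 stringsAsFactors = FALSE),
    scattered = scattered,
    prognostic_gene = prognostic,
    states = states)

  list(expression = omics_matrix(expr, "expression", group),
       cna = omics_matrix(cna, "cna", group),
       methylation = omics_matrix(meth, "methylation", group),
       mirna = omics_matrix(mirna, "mirna", group),
       targets = targets, clinical = clinical, truth = truth)
}

#' Null cohort specification (no planted effects)
#'
#' Convenience wrapper over [cohort_spec()] zeroing every planted
#' tumor/normal effect while keeping cohort dimensions and co-expression
#' structure; used to verify that the pipeline calls nothing on null data.
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec` with all planted effect sizes set to 0.
#' @export
null_cohort_spec <- function(...) {
  cohort_spec(ge_fc_mean = 0, ge_fc_sd = 0, cna_lr = 0, me_fc = 0,
              mirna_fc = 0, passenger_ge_fc = 0, passenger_cna_lr = 0,
              passenger_me_fc = 0, member_ge_fc = 0, scattered_ge_fc = 0,
              prognostic_hr = 1, ...)
}
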