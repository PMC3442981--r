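#' The PYRCORE fixture: a hand-solvable yeast-like fermentation model
#'
#' A 21-metabolite, 23-reaction, two-compartment (extracellular
#' \code{e}, cytosol \code{c}) model of the pyruvate branch point that
#' drives 2,3-butanediol engineering in yeast: glucose is taken up and
#' split glycolytically (two lumped steps, net 2 ATP and 1 NADH per
#' pyruvate), and pyruvate then feeds ethanol (via acetaldehyde, ADH),
#' glycerol (via the triose branch, GPD), acetoin then 2,3-butanediol
#' (PDC-catalysed condensation, then BDH), respiration (P/O ratio 2,
#' oxygen-limited), ATP maintenance, and a biomass sink (1 pyruvate + 3
#' ATP). Isozyme OR rules (\code{ADH1 or ADH3 or ADH5},
#' \code{GPD1 or GPD2}) and a shared gene (\code{PDC1} catalyses both
#' the decarboxylation and the acetoin condensation) mirror the GPR
#' patterns of the genome-scale yeast model. All coefficients are small
#' integers so every optimum under the default environment is an exact
#' small rational: wild-type growth 11 with ethanol 2 / glycerol 7 /
#' butanediol 0; ADH knockout growth 117/11 with butanediol 10/11;
#' ADH+RESP knockout growth 7 with butanediol 2.
#'
#' Acetoin deliberately has no transport or exchange, so acetoin
#' production equals butanediol production and the hand solutions are
#' airtight.
#'
#' @return a validated [MetabolicModel-class].
#' @examples
#' m <- makePyrcore()
#' table(reactionKinds(m))
#' @export
makePyrcore <- function() {
  mets <- c("glc_e", "glc_c", "tp_c", "pyr_c", "nad_c", "nadh_c", "adp_c",
            "atp_c", "glyc_c", "acd_c", "co2_c", "actn_c", "etoh_c",
            "bdo_c", "o2_c", "o2_e", "bio_c", "etoh_e", "glyc_e", "bdo_e",
            "co2_e")
  rx <- function(id, lb, ub, gpr = "", kind = NA_character_)
    data.frame(id = id, lb = lb, ub = ub, gpr = gpr, kind = kind)
  reactions <- rbind(
    rx("EX_glc_e", -10, 0),
    rx("GLCt", 0, 1000),
    rx("GLY1", 0, 1000),
    rx("GLY2", 0, 1000),
    rx("GPD", 0, 1000, "GPD1 or GPD2"),
    rx("PDC", 0, 1000, "PDC1"),
    rx("ACB", 0, 1000, "PDC1"),
    rx("ADH", 0, 1000, "ADH1 or ADH3 or ADH5"),
    rx("BDH", 0, 1000, "BDH1"),
    rx("RESP", 0, 1000),
    rx("O2t", 0, 1000),
    rx("EX_o2_e", -2, 0),
    rx("ATPM", 1, 1000, kind = "maintenance"),
    rx("BIOMASS", 0, 1000, kind = "biomass"),
    rx("EX_bio_c", 0, 1000),
    rx("ETOHt", 0, 1000),
    rx("EX_etoh_e", 0, 1000),
    rx("GLYCt", 0, 1000),
    rx("EX_glyc_e", 0, 1000),
    rx("BDOt", 0, 1000),
    rx("EX_bdo_e", 0, 1000),
    rx("CO2t", 0, 1000),
    rx("EX_co2_e", 0, 1000))
  stoich <- list(
    EX_glc_e = c(glc_e = -1),
    GLCt = c(glc_e = -1, glc_c = 1),
    GLY1 = c(glc_c = -1, tp_c = 2),
    GLY2 = c(tp_c = -1, nad_c = -1, adp_c = -2,
             pyr_c = 1, nadh_c = 1, atp_c = 2),
    GPD = c(tp_c = -1, nadh_c = -1, glyc_c = 1, nad_c = 1),
    PDC = c(pyr_c = -1, acd_c = 1, co2_c = 1),
    ACB = c(pyr_c = -1, acd_c = -1, actn_c = 1, co2_c = 1),
    ADH = c(acd_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1),
    BDH = c(actn_c = -1, nadh_c = -1, bdo_c = 1, nad_c = 1),
    RESP = c(nadh_c = -1, o2_c = -0.5, adp_c = -2, nad_c = 1, atp_c = 2),
    O2t = c(o2_e = -1, o2_c = 1),
    EX_o2_e = c(o2_e = -1),
    ATPM = c(atp_c = -1, adp_c = 1),
    BIOMASS = c(pyr_c = -1, atp_c = -3, adp_c = 3, bio_c = 1),
    EX_bio_c = c(bio_c = -1),
    ETOHt = c(etoh_c = -1, etoh_e = 1),
    EX_etoh_e = c(etoh_e = -1),
    GLYCt = c(glyc_c = -1, glyc_e = 1),
    EX_glyc_e = c(glyc_e = -1),
    BDOt = c(bdo_c = -1, bdo_e = 1),
    EX_bdo_e = c(bdo_e = -1),
    CO2t = c(co2_c = -1, co2_e = 1),
    EX_co2_e = c(co2_e = -1))
  metabolicModel(mets, reactions, stoich,
                 genes = c("ADH1", "ADH3", "ADH5", "GPD1", "GPD2",
                           "PDC1", "BDH1"),
                 objective = "BIOMASS")
}

#' Specification for the seeded random-model generator
#'
#' @param seed integer RNG seed; identical seeds give identical models.
#' @param n_segments number of chain reactions between the substrate and
#'   the central hub metabolite (>= 1).
#' @param n_cofactor_pairs 1 (redox only) or 2 (redox + energy carrier,
#'   the default; only then does the model carry a maintenance reaction).
#' @param n_branches number of fermentation branch products (>= 1); the
#'   first branch is always a pure redox valve so generated models stay
#'   growth-feasible.
#' @param bound_magnitude numeric bound used for "unconstrained"
#'   directions (default 1000).
#' @return a list of class \code{"randomModelSpec"}.
#' @seealso [makeRandomModel()]
#' @export
randomModelSpec <- function(seed = 42L, n_segments = 2L,
                            n_cofactor_pairs = 2L, n_branches = 3L,
                            bound_magnitude = 1000) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (!n_cofactor_pairs %in% 1:2)
    stop("n_cofactor_pairs must be 1 or 2")
  if (n_branches < 1L) stop("n_branches must be >= 1")
  structure(list(seed = as.integer(seed), n_segments = as.integer(n_segments),
                 n_cofactor_pairs = as.integer(n_cofactor_pairs),
                 n_branches = as.integer(n_branches),
                 bound_magnitude = bound_magnitude),
            class = "randomModelSpec")
}

withLocalSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a seeded random fermentation-like model
#'
#' Builds a stoichiometrically consistent model from balanced templates
#' rather than random matrices, so every draw is growth-feasible without
#' a repair step: a substrate uptake chain producing a hub metabolite
#' with redox (and optionally energy) cofactor coupling, fermentation
#' branches draining the hub (with randomized coefficients, GPR rules
#' drawn from a small gene pool, and occasional two-step pathways and
#' shared genes), an oxygen-limited cofactor recycler, maintenance, and
#' a biomass sink. Branch products are exported through transport +
#' exchange pairs named \code{<PROD>t} / \code{EX_<prod>_e}.
#'
#' @param spec a [randomModelSpec()].
#' @return a validated [MetabolicModel-class]; identical specs give
#'   identical models.
#' @export
makeRandomModel <- function(spec = randomModelSpec()) {
  stopifnot(inherits(spec, "randomModelSpec"))
  withLocalSeed(spec$seed, {
    M <- spec$bound_magnitude
    energy <- spec$n_cofactor_pairs == 2L
    u <- sample(5:15, 1)                       # substrate uptake capacity
    o2max <- sample(1:4, 1)                    # oxygen uptake capacity
    s1 <- sample(1:3, 1)                       # chain split coefficient
    na <- if (energy) sample(1:2, 1) else 0    # ATP per hub formed
    nr <- if (energy) sample(1:2, 1) else 0    # ATP per redox respired
    nb <- if (energy) sample(2:3, 1) else 0    # ATP per biomass
    pool <- paste0("g", 1:8)

    mets <- c("sub_e", "sub_c", "hub_c", "ox_c", "rd_c", "o2_e", "o2_c",
              "bio_c")
    if (energy) mets <- c(mets, "lp_c", "hp_c")
    rxn <- list(); sto <- list()
    addr <- function(id, lb, ub, co, gpr = "", kind = NA_character_) {
      rxn[[id]] <<- data.frame(id = id, lb = lb, ub = ub, gpr = gpr,
                               kind = kind)
      sto[[id]] <<- co
    }
    addr("EX_sub_e", -u, 0, c(sub_e = -1))
    addr("SUBt", 0, M, c(sub_e = -1, sub_c = 1))

    # chain: sub_c -> ... -> hub_c, redox/energy made on the last step
    last <- "sub_c"; mult <- 1
    for (k in seq_len(spec$n_segments)) {
      final <- k == spec$n_segments
      out <- if (final) "hub_c" else paste0("m", k, "_c")
      if (!final) mets <- c(mets, out)
      co <- stats::setNames(-1, last)
      if (final) {
        co[out] <- 1; co["ox_c"] <- -1; co["rd_c"] <- 1
        if (energy) { co["lp_c"] <- -na; co["hp_c"] <- na }
      } else if (k == 1L) {
        co[out] <- s1; mult <- s1
      } else co[out] <- 1
      addr(paste0("CHAIN", k), 0, M, co)
      last <- out
    }

    # fermentation branches off the hub
    shared <- if (spec$n_branches >= 2L && stats::runif(1) < 0.5)
      sample(pool, 1) else NULL
    for (b in seq_len(spec$n_branches)) {
      prod <- paste0("p", b)
      redox <- if (b == 1L) 1L else sample(0:1, 1)
      gpr <- if (b == 1L && !is.null(shared)) shared
        else switch(sample(4, 1),
          sample(pool, 1),
          paste(sample(pool, sample(2:3, 1)), collapse = " or "),
          paste(sample(pool, 2), collapse = " and "),
          sprintf("%s and (%s or %s)", sample(pool, 1), sample(pool, 1),
                  sample(pool, 1)))
      if (b == 2L && !is.null(shared))
        gpr <- paste0(shared, " or ", sample(pool, 1))
      two_step <- b >= 2L && stats::runif(1) < 0.4
      if (two_step) {
        mid <- paste0("i", b, "_c")
        mets <- c(mets, mid, paste0(prod, "_c"), paste0(prod, "_e"))
        addr(paste0("B", b, "a"), 0, M,
             stats::setNames(c(-1, 1), c("hub_c", mid)), gpr = gpr)
        co <- stats::setNames(c(-1, 1), c(mid, paste0(prod, "_c")))
        if (redox) { co["rd_c"] <- -1; co["ox_c"] <- 1 }
        addr(paste0("B", b, "b"), 0, M, co, gpr = sample(pool, 1))
      } else {
        mets <- c(mets, paste0(prod, "_c"), paste0(prod, "_e"))
        co <- stats::setNames(c(-1, 1), c("hub_c", paste0(prod, "_c")))
        if (redox) { co["rd_c"] <- -1; co["ox_c"] <- 1 }
        addr(paste0("B", b), 0, M, co, gpr = gpr)
      }
      addr(paste0(toupper(prod), "t"), 0, M,
           stats::setNames(c(-1, 1), paste0(prod, c("_c", "_e"))))
      addr(paste0("EX_", prod, "_e"), 0, M,
           stats::setNames(-1, paste0(prod, "_e")))
    }

    co <- c(rd_c = -1, o2_c = -0.5, ox_c = 1)
    if (energy) { co["lp_c"] <- -nr; co["hp_c"] <- nr }
    addr("RESP", 0, M, co)
    addr("O2t", 0, M, c(o2_e = -1, o2_c = 1))
    addr("EX_o2_e", -o2max, 0, c(o2_e = -1))
    if (energy)
      addr("ATPM", 1, M, c(hp_c = -1, lp_c = 1), kind = "maintenance")
    co <- c(hub_c = -1, bio_c = 1)
    if (energy) { co["hp_c"] <- -nb; co["lp_c"] <- nb }
    addr("BIOMASS", 0, M, co, kind = "biomass")
    addr("EX_bio_c", 0, M, c(bio_c = -1))

    metabolicModel(mets, do.call(rbind, rxn), sto, objective = "BIOMASS")
  })
}

#' Brute-force knockout design (the enumeration oracle)
#'
#' Enumerates every subset of the candidate reactions of size at most K,
#' evaluates each by lexicographic FBA (maximize growth, then maximize
#' the target flux at that growth), and returns the feasible subset with
#' the largest target flux. Ties are broken by fewer knockouts, then by
#' lexicographic reaction ids, matching [solveOptKnock()]'s determinism
#' contract. This routine is deliberately independent of the MILP: it is
#' the ground truth the bilevel solver is tested against.
#'
#' @param model a [MetabolicModel-class].
#' @param env an [EnvironmentSpec-class] or NULL.
#' @param target_id target reaction id.
#' @param K maximum number of simultaneous deletions.
#' @param candidates candidate reaction ids; defaults to
#'   [buildCandidateSet()].
#' @param f_min minimum admissible growth (absolute units).
#' @param guard refuse to enumerate more than this many subsets
#'   (default 50000).
#' @return list with \code{reactions}, \code{growth}, \code{target}.
#' @export
bruteForceDesign <- function(model, env = NULL, target_id, K,
                             candidates = NULL, f_min = 0,
                             guard = 50000L) {
  if (is.null(candidates))
    candidates <- buildCandidateSet(model, env, f_min)$candidates
  candidates <- sort(as.character(candidates))
  n <- length(candidates)
  total <- sum(choose(n, 0:min(K, n)))
  if (total > guard)
    stop("enumeration guard exceeded (", total, " subsets); reduce K or ",
         "the candidate set")
  best <- NULL
  consider <- function(del) {
    m2 <- applyKnockouts(model, reactions = del)
    g <- solveFBA(m2, env)
    if (g@status != "optimal" || g@objective < f_min - 1e-9) return()
    t2 <- fixAndOptimize(m2, env, objectiveId(model), target_id)
    if (t2@status != "optimal") return()
    cand <- list(reactions = del, growth = g@objective,
                 target = t2@objective)
    if (is.null(best)) { best <<- cand; return() }
    d <- cand$target - best$target
    better <- d > 1e-9 ||
      (abs(d) <= 1e-9 && (length(del) < length(best$reactions) ||
        (length(del) == length(best$reactions) &&
         paste(del, collapse = ",") <
         paste(best$reactions, collapse = ","))))
    if (better) best <<- cand
  }
  consider(character())
  for (k in seq_len(min(K, n)))
    for (del in utils::combn(candidates, k, simplify = FALSE))
      consider(del)
  if (is.null(best))
    stop("no feasible deletion set (including the empty set) at f_min = ",
         f_min)
  best
}
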