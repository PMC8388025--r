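# Deterministic toy models and scenarios used by tests, examples and the
# shipped configurations. No external data is required.

#' Toy metabolic model "TOY1"
#'
#' A four-metabolite branched network: substrate A is taken up (R_up, cap
#' 10) and split into B (R1, gene g1) and C (R2, gene g2); biomass consumes
#' B and C 1:1; B can instead be drained to product P (R3, gpr
#' "g3 or (g1 and g4)") and exported (EX_P). Wild-type FBA growth is 5.0
#' with no product; capping R2 frees B for product.
#'
#' @return a `metabolic_model` with objective `R_biomass`
#' @export
toy_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B", "C", "P"),
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = list(
      R_up = list(stoichiometry = c(A = 1), lb = 0, ub = 10),
      R1 = list(stoichiometry = c(A = -1, B = 1), lb = 0, ub = 10,
                gpr = "g1"),
      R2 = list(stoichiometry = c(A = -1, C = 1), lb = 0, ub = 10,
                gpr = "g2"),
      R3 = list(stoichiometry = c(B = -1, P = 1), lb = 0, ub = 10,
                gpr = "g3 or (g1 and g4)"),
      R_biomass = list(stoichiometry = c(B = -1, C = -1), lb = 0, ub = 10),
      EX_P = list(stoichiometry = c(P = -1), lb = 0, ub = 10)),
    genes = c("g1", "g2", "g3", "g4"),
    objective = "R_biomass")
}

#' Toy Boolean regulatory network "TOYREG" for [toy_model()]
#'
#' Two rules: TF `t1` is activated by environment signal `env_s1`, and
#' metabolic gene `g2` is repressed by `t1`. With the signal on, g2 (hence
#' reaction R2) shuts down and growth collapses; deleting the TF rescues
#' the wild-type phenotype.
#'
#' @return a `regulatory_network`
#' @export
toy_regulatory <- function() {
  regulatory_network(
    rules = c(t1 = "env_s1", g2 = "not t1"),
    regulators = "t1",
    signals = "env_s1")
}

#' Toy enzyme parameters "TOY1-ENZ" for [toy_model()]
#'
#' R1 and R2 each cost 0.1 g/gDW per flux unit (kcat 10 /h, MW 1 kDa);
#' the shared protein pool is 0.6 g/gDW, so R1 + R2 <= 6 and constrained
#' growth is 3.0.
#'
#' @return an `enzyme_params` object
#' @export
toy_enzymatic <- function() {
  enzyme_params(data.frame(reaction_id = c("R1", "R2"),
                           kcat_per_h = c(10, 10),
                           mw_kda = c(1, 1),
                           stringsAsFactors = FALSE),
                pool = 0.6)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random branched toy model generator
#'
#' Builds a substrate-to-biomass network of `n_pathways` parallel linear
#' pathways (lengths 1-3, random capacities in \[1, 10\], one-gene GPRs)
#' plus a product branch, guaranteed to have a feasible wild type with
#' positive growth. With `n_pathways = 1` the FBA optimum equals the
#' minimum capacity along the single chain.
#'
#' @param n_pathways number of parallel pathways (1-20)
#' @param seed RNG seed; the caller's RNG state is untouched
#' @return a `metabolic_model` with objective `R_biomass`
#' @export
random_model <- function(n_pathways, seed) {
  stopifnot(n_pathways >= 1, n_pathways <= 20)
  with_local_seed(seed, {
    mets <- "S"
    rxns <- list(R_up = list(stoichiometry = c(S = 1), lb = 0,
                             ub = round(stats::runif(1, 2, 12), 3)))
    genes <- character()
    for (i in seq_len(n_pathways)) {
      len <- sample(1:3, 1)
      prev <- "S"
      for (j in seq_len(len)) {
        met <- sprintf("M%d_%d", i, j)
        mets <- c(mets, met)
        rid <- sprintf("R%d_%d", i, j)
        g <- sprintf("g%d_%d", i, j)
        st <- c(-1, 1); names(st) <- c(prev, met)
        rxns[[rid]] <- list(stoichiometry = st, lb = 0,
                            ub = round(stats::runif(1, 0.5, 8), 3),
                            gpr = g)
        genes <- c(genes, g)
        prev <- met
      }
      # feed the biomass precursor
      st <- c(-1, 1); names(st) <- c(prev, "BM")
      rxns[[sprintf("R%d_bm", i)]] <- list(stoichiometry = st, lb = 0,
                                           ub = DEFAULT_BOUND)
    }
    mets <- c(mets, "BM", "Px")
    st <- c(S = -1, Px = 1)
    rxns$R_prod <- list(stoichiometry = st, lb = 0, ub = 10,
                        gpr = "g_prod")
    rxns$EX_P <- list(stoichiometry = c(Px = -1), lb = 0, ub = 10)
    rxns$R_biomass <- list(stoichiometry = c(BM = -1), lb = 0,
                           ub = DEFAULT_BOUND)
    genes <- c(genes, "g_prod")
    metabolic_model(
      metabolites = data.frame(id = mets, compartment = "c",
                               stringsAsFactors = FALSE),
      reactions = rxns, genes = genes, objective = "R_biomass")
  })
}

#' Export a fixture scenario to on-disk files
#'
#' Writes the toy model in the JSON dialect and, optionally, the
#' regulatory rule file and enzyme parameter TSV alongside it, so that
#' command-line examples can run on them.
#'
#' @param dir output directory (created if needed)
#' @param regulatory,enzymes also write TOYREG rules / TOY1-ENZ table
#' @return named character vector of written paths
#' @export
export_fixture <- function(dir, regulatory = FALSE, enzymes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(model = file.path(dir, "toy1.json"))
  write_model_json(toy_model(), out[["model"]])
  if (regulatory) {
    out["regulatory"] <- file.path(dir, "toyreg.txt")
    write_regulatory_rules(toy_regulatory(), out[["regulatory"]])
  }
  if (enzymes) {
    out["enzymes"] <- file.path(dir, "toy1_enz.tsv")
    write_enzyme_tsv(toy_enzymatic(), out[["enzymes"]])
  }
  out
}
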