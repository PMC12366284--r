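# In-package reference fixtures: the first catalytic step of alpha-amylase
# (whose first arrow's one-away environment serializes to the reference
# SMARTS string) and the alpha-amylase / endo-xyloglucan transferase pair of
# retaining-glycosidase mechanisms used as the worked similarity example.
#
# Both enzymes run a double-displacement mechanism in two concerted steps of
# three curly arrows each. Step 1 (glycosylation) is identical in the two
# enzymes: a carboxylate oxygen attacks the anomeric carbon, the glycosidic
# C-O bond breaks, and the leaving oxygen abstracts the proton of the acid
# residue. Step 2 differs only in the incoming nucleophile: water
# (hydrolysis, alpha-amylase) versus a sugar hydroxyl (transglycosylation,
# endo-xyloglucan transferase). Proton transfers are drawn condensed as a
# single arrow (lone pair to the proton in step 1; O-H bond to the incipient
# O-H bond in step 2) so that each step carries exactly three arrows.

# Atom ids shared by the step builders
#  1 C1 anomeric C     2 O5 ring O        3 C5          4 H1
#  5 C2                6 H2               7 O2 hydroxyl
#  8 Oglyc glycosidic O  9 Cagl aglycone C  10 Hagl  11 Oagl  12 Cagl2
# 13 Onuc nucleophile O  14 Ccarb  15 Ocarb(=O)  16 Cbeta
# 17 OGlu acid O  18 HGlu  19 CGluC  20 OGlud(=O)  21 CGlub
# 30 attacking O (water / acceptor sugar)  31 its H  32 Hw2 | 33-36 acceptor C shell

glyco_step1 <- function() {
  C <- 6L; H <- 1L; O <- 8L
  atoms <- data.frame(
    atom_id = c(1:21),
    element = c(C, O, C, H, C, H, O,  O, C, H, O, C,
                O, C, O, C,  O, H, C, O, C),
    charge  = c(rep(0L, 12), -1L, rep(0L, 8)))
  bonds <- data.frame(
    a     = c(1, 2, 1, 1, 5, 5, 1, 8,  9,  9,  9, 13, 14, 14, 17, 17, 19, 19),
    b     = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 14, 15, 16, 18, 19, 20, 21),
    order = c(rep("single", 12), "double", "single", "single", "single",
              "double", "single"))
  arrows <- list(
    # nucleophilic attack: carboxylate lone pair -> incipient O-C bond
    curly_arrow(2L, arrow_atom(13), arrow_incipient(13, 1)),
    # glycosidic bond cleavage: C1-Oglyc bond -> leaving oxygen
    curly_arrow(2L, arrow_bond(1, 8), arrow_atom(8)),
    # proton abstraction: leaving-oxygen lone pair -> acid proton
    curly_arrow(2L, arrow_atom(8), arrow_atom(18)))
  catalytic_step(1L, site_state(atoms, bonds), arrows)
}

# step 2 shares the glycosyl-enzyme intermediate; `acceptor` switches the
# incoming nucleophile between water and a sugar hydroxyl
glyco_step2 <- function(acceptor = c("water", "sugar")) {
  acceptor <- match.arg(acceptor)
  C <- 6L; H <- 1L; O <- 8L
  base <- data.frame(
    atom_id = c(1:7, 13:17, 19:21),
    element = c(C, O, C, H, C, H, O,  O, C, O, C, O, C, O, C),
    charge  = c(rep(0L, 11), -1L, 0L, 0L, 0L))
  nuc <- if (acceptor == "water") {
    data.frame(atom_id = c(30L, 31L, 32L), element = c(O, H, H),
               charge = 0L)
  } else {
    data.frame(atom_id = c(30L, 31L, 33L, 34L, 35L, 36L),
               element = c(O, H, C, H, O, C), charge = 0L)
  }
  bonds <- data.frame(
    a     = c(1, 2, 1, 1, 5, 5,  1, 13, 14, 14, 17, 19, 19, 30, 30),
    b     = c(2, 3, 4, 5, 6, 7, 13, 14, 15, 16, 19, 20, 21, 31,
              if (acceptor == "water") 32 else 33),
    order = c(rep("single", 8), "double", "single", "single", "double",
              "single", "single", "single"))
  if (acceptor == "sugar") {
    bonds <- rbind(bonds, data.frame(a = c(33, 33, 33), b = c(34, 35, 36),
                                     order = "single"))
  }
  arrows <- list(
    # nucleophilic attack on the anomeric carbon
    curly_arrow(2L, arrow_atom(30), arrow_incipient(30, 1)),
    # cleavage of the covalent glycosyl-enzyme bond
    curly_arrow(2L, arrow_bond(1, 13), arrow_atom(13)),
    # deprotonation of the attacking hydroxyl by the catalytic base
    curly_arrow(2L, arrow_bond(30, 31), arrow_incipient(31, 17)))
  catalytic_step(2L, site_state(rbind(base, nuc), bonds), arrows)
}

#' Reference catalytic step: glycosylation of alpha-amylase
#'
#' Three curly arrows: nucleophilic attack by a carboxylate oxygen on the
#' anomeric (glycosidic) carbon, cleavage of the glycosidic C-O bond, and
#' proton transfer from the catalytic acid to the leaving oxygen. The first
#' arrow's one-away environment serializes to the reference SMARTS
#' `[#6]-[#8&-:23].[#8]-[#6:22](-[#8])(-[#1])-[#6]`.
#'
#' @return a [catalytic_step()].
#' @export
make_fig1_step <- function() glyco_step1()

#' Worked-example mechanism pair: alpha-amylase and endo-xyloglucan
#' transferase
#'
#' Two retaining glycosidases encoded as 2-step, 3-arrow-per-step
#' mechanisms. Their two-away arrow-env sets have sizes 6 and 6 with
#' intersection 4 (union 8) and their pooled chain sets sizes 4 and 4 with
#' intersection 2 (union 6), giving an unordered similarity of 0.50 and an
#' ordered similarity of 0.41667 (displayed 42%). These cardinalities are
#' self-checked at construction; any drift fails loudly.
#'
#' @return named list with elements `amylase` and `xet`, each a
#'   [mechanism()] carrying EC and CATH annotations.
#' @export
make_glycosidase_pair <- function() {
  amylase <- mechanism(
    "alpha-amylase",
    list(glyco_step1(), glyco_step2("water")),
    annotations = list(ec = "3.2.1.1", cath = "3.20.20.80"))
  xet <- mechanism(
    "endo-xyloglucan-transferase",
    list(glyco_step1(), glyco_step2("sugar")),
    annotations = list(ec = "2.4.1.207", cath = "2.60.120.200"))
  stop_if_invalid(amylase)
  stop_if_invalid(xet)

  ea <- mechanism_envs(amylase, "two_away")
  eb <- mechanism_envs(xet, "two_away")
  ca <- mechanism_chains(amylase, "two_away")
  cb <- mechanism_chains(xet, "two_away")
  ok <- length(ea) == 6L && length(eb) == 6L &&
    length(intersect(ea, eb)) == 4L &&
    length(ca) == 4L && length(cb) == 4L &&
    length(intersect(ca, cb)) == 2L
  if (!ok) {
    stop("glycosidase-pair fixture drifted from its reference cardinalities ",
         sprintf("(envs %d/%d shared %d, chains %d/%d shared %d)",
                 length(ea), length(eb), length(intersect(ea, eb)),
                 length(ca), length(cb), length(intersect(ca, cb))))
  }
  list(amylase = amylase, xet = xet)
}
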