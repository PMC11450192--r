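# Shared fixtures, built once per test run.

# TOY-CORE with planted truth (oracle verification exercised in its own test)
TOY <- make_toy_gem(verify = FALSE)

# a three-reaction linear chain whose FBA optimum is hand-derivable:
# EX_a (uptake U) -> transport -> A, 2 A -> grow; max growth = U/2
micro_chain <- function(uptake = 10) {
  mets <- data.frame(id = c("a_e", "a_c"), name = c("a", "a"),
                     compartment = c("e", "c"), formula = c("C1", "C1"),
                     charge = 0, deltaG0 = NA_real_, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_a", "At", "GROW"), name = "",
                     lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                     subsystem = "", deltaG0 = NA_real_,
                     pseudo = c(TRUE, FALSE, TRUE),
                     gpr = c("", "gT", ""), stringsAsFactors = FALSE)
  stoich <- list(EX_a = c(a_e = -1), At = c(a_e = -1, a_c = 1),
                 GROW = c(a_c = -2))
  gem("micro-chain", c(e = "extracellular", c = "cytoplasm"),
      mets, rxns, stoich, objective = "GROW")
}

# two equal-yield routes from a to b; route 1 uses one reaction, route 2 two
micro_two_routes <- function() {
  mets <- data.frame(id = c("a_c", "m_c", "b_c"), name = "",
                     compartment = "c", formula = "C1", charge = 0,
                     deltaG0 = NA_real_, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("SRC", "R1", "R2a", "R2b", "SNK"), name = "",
                     lb = 0, ub = c(10, 1000, 1000, 1000, 1000),
                     subsystem = "", deltaG0 = NA_real_,
                     pseudo = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                     gpr = c("", "g1", "g2", "g3", ""), stringsAsFactors = FALSE)
  stoich <- list(SRC = c(a_c = 1), R1 = c(a_c = -1, b_c = 1),
                 R2a = c(a_c = -1, m_c = 1), R2b = c(m_c = -1, b_c = 1),
                 SNK = c(b_c = -1))
  gem("micro-two-routes", c(c = "cytoplasm"), mets, rxns, stoich,
      objective = "SNK")
}
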