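# Shared fixtures: a fast-mixing individual that reduces the whole-body model
# to an effective one-compartment system (organ equilibration times of
# seconds against elimination half-lives of hours), and minimal drugs used by
# the analytic oracles. All built in code.

# Individual whose organ flows are so high that the body behaves as one
# well-mixed compartment of volume sum(V); liver receives 3q (hepatic artery
# q + portal 2q).
fast_mix_individual <- function(q = 200) {
  ind <- default_individual()
  org <- ind$organs
  org$blood_flow <- ifelse(org$name == "liver", 3 * q, q)
  co <- 11 * q   # hepatic artery q + 10 non-liver systemic organs
  org$blood_flow[org$name == "lung"] <- co
  ind$organs <- org
  ind$cardiac_output <- co
  validate_individual(ind)
}

# total effective volume of the fast-mixing reduction for Kp = 1, B:P = 1
one_compartment_volume <- function(ind) {
  sum(ind$organs$volume) + ind$blood$arterial_volume + ind$blood$venous_volume
}

# drug eliminated only by unspecific hepatic clearance; with fu = 1, Kp = 1
# its plasma clearance is cl_apparent (up to a 1/Q_liver flow correction)
mono_drug <- function(cl_apparent = 0.1, fu = 1, name = "mono") {
  drug(name, molecular_weight = 300, fu = fu,
       kp_map = list(default = 1),
       pathways = list(pathway("UNSPECIFIC", "unspecific_hepatic",
                               cl_apparent = cl_apparent)))
}

# victim with a single linear CYP2C19 pathway (fraction metabolized 1)
cyp_victim <- function(cl_int = 1.6, fu = 1, enzyme = "CYP2C19",
                       name = "victim") {
  drug(name, molecular_weight = 300, fu = fu, kp_map = list(default = 1),
       pathways = list(pathway(enzyme, "linear", cl_int = cl_int)))
}

# inert perpetrator: no clearance pathways, so an IV bolus settles to a
# constant concentration - a clamped inhibitor
clamped_inhibitor <- function(inhibitions, name = "perp", fu = 1) {
  drug(name, molecular_weight = 300, fu = fu, kp_map = list(default = 1),
       inhibitions = inhibitions)
}

# fast solver for tests that do not probe integration accuracy
test_solver <- function() solver_settings(rtol = 1e-6, atol = 1e-9)

# simulate a single drug with one regimen on an individual
sim1 <- function(d, regimen, ind, t_end, grid = NULL,
                 solver = solver_settings()) {
  sys <- assemble(ind, list(d), list(regimen), solver = solver)
  simulate_pbpk(sys, t_end, grid)
}
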