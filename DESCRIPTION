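Package: LipidSites
Title: Mapping Fatty-Acid Binding Sites on Membrane Proteins from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to localize lipid (fatty-acid) interaction sites on membrane
    proteins from molecular-dynamics trajectories: per-residue total interaction
    time and longest contact lifetime with Tukey-fence (Q3 + 1.5 IQR) calling of
    high-contact and stable-contact residues, per-lipid statistics with
    upper-quartile and constant-binder classification, voxel occupancy grids and
    layered occupancy maps, slab contact profiles with species fold-enrichment,
    lateral radial distribution functions, Jarvis-Patrick and GROMOS
    conformational clustering with representative-pose extraction,
    distance-based hydrogen-bond, salt-bridge and hydrophobic-contact detection,
    and electrophysiology curve fitting (Boltzmann conductance-voltage, Hill
    concentration-response, single-exponential kinetics). Includes a synthetic
    trajectory and curve generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, bio3d, minpack.lm, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
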