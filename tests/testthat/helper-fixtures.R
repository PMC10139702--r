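# Hand-constructed fixtures shared by convergence/pipeline tests.

# Four-tip tree with two focal tips (f1, f2) in disjoint clades, each with
# a short-branched context tip (a, b) that pins down the focal parent's
# ancestral state.
fixture_tree <- function() {
  ape::read.tree(text = "((f1:0.30,a:0.02):0.10,(f2:0.30,b:0.02):0.10);")
}

# Alignment with exactly one convergent site (parents S and T, both focal
# tips derived A), one parallel site (parents both S, both focal tips A),
# one shared-but-different-derived site (no event), and background sites.
fixture_alignment <- function() {
  sites <- rbind(
    #        f1   a    f2   b
    conv  = c("A", "S", "A", "T"),
    par   = c("A", "S", "A", "S"),
    none  = c("A", "S", "V", "S"),
    bg1   = c("S", "S", "S", "S"),
    bg2   = c("L", "L", "L", "L"),
    bg3   = c("K", "K", "K", "K"))
  m <- t(sites)
  rownames(m) <- c("f1", "a", "f2", "b")
  m
}

fixture_set <- function(mode = "all") {
  aaconv::focal_set("focal-2", c("f1", "f2"), mode = mode)
}

# Standard study configuration pieces.
study_sets <- function() {
  tips <- aaconv::myrmecophagy_tips()
  list(all3 = aaconv::focal_set("myrmecophagous-3", tips$focal, "all"),
       pw3 = aaconv::focal_set("myrmecophagous-3-pw", tips$focal,
                               "pairwise"),
       sis = aaconv::focal_set("sisters-5", tips$sisters, "all"),
       sis_pw = aaconv::focal_set("sisters-5-pw", tips$sisters, "pairwise"))
}
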