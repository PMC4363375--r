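# Shared pedigree and variant-record builders for the test suite.

trioPed <- function(affection = c("unknown", "unknown", "unknown")) {
  Pedigree(id = c("dad", "mum", "kid"),
           father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
           sex = c("male", "female", "female"), affection = affection)
}

nuclearPed <- function(nKids = 2) {
  kids <- paste0("k", seq_len(nKids))
  Pedigree(id = c("dad", "mum", kids),
           father = c(NA, NA, rep("dad", nKids)),
           mother = c(NA, NA, rep("mum", nKids)),
           sex = c("male", "female", rep("unknown", nKids)))
}

halfSibPed <- function() {
  Pedigree(id = c("dad", "m1", "m2", "c1", "c2"),
           father = c(NA, NA, NA, "dad", "dad"),
           mother = c(NA, NA, NA, "m1", "m2"),
           sex = c("male", "female", "female", "unknown", "unknown"))
}

# grandparental couple, two sibs married out, their children are first
# cousins; optionally the cousins marry and have a child
cousinPed <- function(withChild = FALSE) {
  id     <- c("g1", "g2", "p1", "p2", "s1", "s2", "c1", "c2")
  father <- c(NA,   NA,   "g1", "g1", NA,   NA,   "p1", "p2")
  mother <- c(NA,   NA,   "g2", "g2", NA,   NA,   "s1", "s2")
  sex    <- c("male", "female", "male", "male", "female", "female",
              "male", "female")
  if (withChild) {
    id <- c(id, "x"); father <- c(father, "c1"); mother <- c(mother, "c2")
    sex <- c(sex, "unknown")
  }
  Pedigree(id = id, father = father, mother = mother, sex = sex)
}

# 12-member three-generation family, small enough for exact enumeration
# (7 non-founders = 14 meioses)
twelvePed <- function() {
  id     <- c("A1", "A2", "B1", "B2", "E1",
              "C1", "C2", "D1", "K1", "K2", "K3", "K4")
  father <- c(NA, NA, NA, NA, NA,
              "A1", "A1", "B1", "C1", "C1", "C1", "C2")
  mother <- c(NA, NA, NA, NA, NA,
              "A2", "A2", "B2", "D1", "D1", "D1", "E1")
  sex    <- c("male", "female", "male", "female", "female",
              "male", "male", "female", "unknown", "unknown", "unknown",
              "unknown")
  Pedigree(id = id, father = father, mother = mother, sex = sex)
}

# variant-record rows with passing defaults; override any field
makeRecords <- function(n = 1, sample_id = "S01", chrom = "1",
                        pos = seq_len(n) * 100L, ref = "A", alt = "T",
                        gene = "GENE1", consequence = "missense",
                        known = FALSE, depth = 60L, variant_reads = 30L,
                        unique_start_sites = 10L) {
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             pos = rep_len(pos, n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), gene = rep_len(gene, n),
             consequence = rep_len(consequence, n),
             known = rep_len(known, n), depth = rep_len(depth, n),
             variant_reads = rep_len(variant_reads, n),
             unique_start_sites = rep_len(unique_start_sites, n))
}

# concatenate independent simulated families into one Pedigree
concatFamilies <- function(nFam, cfgMaker, seedBase = 1000) {
  fams <- lapply(seq_len(nFam), function(k) {
    p <- simulatePedigree(cfgMaker(seedBase + k))
    d <- individuals(p)
    pre <- function(x) ifelse(is.na(x), NA, paste0("F", k, "_", x))
    d$id <- paste0("F", k, "_", d$id)
    d$father <- pre(d$father); d$mother <- pre(d$mother)
    d
  })
  d <- do.call(rbind, fams)
  Pedigree(id = d$id, father = d$father, mother = d$mother, sex = d$sex,
           affection = d$affection)
}
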