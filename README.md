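# pocketevo

Evolutionary scenarios for receptor binding pockets that predate their
ligands.

Many membrane receptors are evolutionarily older than their endogenous
ligands. `pocketevo` asks how such a receptor's ligand-binding pocket
evolved across the animal tree before and after the ligand appeared, and
classifies each receptor–ligand pair into one of three histories:

* **S1** — the pocket pre-existed and was under purifying selection all
  along (an ancestral, unrelated ligand was presumably replaced);
* **S2** — the pocket was acquired progressively, with positive selection
  after the ligand appeared;
* **S3** — a pocket existed but was reshuffled around the time the ligand
  appeared, then frozen by purifying selection.

From a receptor–ligand 3D complex (PDB), an in-frame codon alignment of
receptor orthologs (FASTA) with a designated mammalian reference, a
phylogeny (newick) and an ordered taxonomic branch scheme (YAML), the
package computes per-branch indexes and applies rule-based scenario
criteria:

* **%ID BP / %ID Mol** — mean percent identity of each branch's species to
  the mammalian reference over the pocket columns / the whole sequence,
  with a paired Student test deciding whether the pocket is more conserved
  than the rest of the molecule;
* **N** — the within-branch count of amino-acid differences at pocket
  columns (distinct residues per column, minus one, summed);
* **ω (dN/dS) of the pocket, per branch** — a counting estimator: Fitch
  parsimony ancestral codons, substitutions on each branch's edges
  classified synonymous / non-synonymous through stop-avoiding shortest
  mutational pathways, normalized by Nei–Gojobori-style site counts
  (dn = Nd/N, ds = Sd/S, ω = dn/ds);
* **per-site selection calls** — an exact binomial test of each column's
  non-synonymous excess against its neutral site-count expectation, used to
  flag positively selected pocket sites.

A branch- and site-class aware codon simulator (ten-group clade ladder,
pocket vs background ω schedules per scenario) generates synthetic receptor
families so the entire pipeline and the classifier are validated without
external data.

## Worked example

Generate a synthetic receptor family under the reshuffling scenario, compute
its index table, and classify it:

```r
library(pocketevo)

case <- generateCase("S3", seed = 2)          # 30 species, 500 codons, 25-codon pocket
tab  <- computeIndexTable(case$alignment, case$tree, case$scheme, case$pocket)
call <- classifyScenario(tab)
writeLines(renderReport(tab, call))
```

```
Per-branch binding-pocket indexes (ancestral -> mammals)
group               %ID_BP   %ID_Mol    omega       dN     N        p      direction  ligand
metazoans             12.0      16.3    3.576    0.526    13   0.2061           none      no
bilaterians           14.7      19.2    1.636    0.746    13   0.2315           none      no
protostomians         26.7      21.3    1.246    0.586    14   0.0464  pocket-higher      no
chordates             28.0      24.6    1.710    0.603    11   0.2528           none     yes
vertebrates           92.0      32.1    0.147    0.103     0   0.0000  pocket-higher     yes
teleosts              98.7      36.2    0.020    0.017     1   0.0002  pocket-higher     yes
sarcopterygians      100.0      41.3    0.000    0.000     0   0.0001  pocket-higher     yes
amphibians            89.3      50.6    0.080    0.052     1   0.0009  pocket-higher     yes
sauropsids            97.3      59.3    0.024    0.017     1   0.0009  pocket-higher     yes
mammals              100.0      90.3    0.000    0.000     0   0.0197  pocket-higher     yes
...
Scenario call: S3
```

Reading the table: before the ligand (metazoans–protostomians) the pocket
shares only 12–27% identity with the mammalian interface, ω exceeds 1 and
within-branch N is high — the pocket is drifting. In the chordate branch,
where the ligand first appears, ω is still above 1 (reshuffling). From
vertebrates on, pocket identity jumps above 90%, ω collapses toward 0 and
N to 0: the remodelled pocket is frozen by purifying selection. The
criterion audit appended to the report lists every scenario criterion with
its supporting numbers.

The same pipeline runs from files
(`runPipeline(alignment =, tree =, scheme =, pocket = | pdb =, ...)`), and
`extractInterface()` derives the pocket from a PDB complex with a 5 Å
heavy-atom contact cutoff.

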