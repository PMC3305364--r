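Package: ClickMol
Title: Geometric In Silico Click-Chemistry Product Construction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects click-reactive functional groups (azides, alkynes,
    epoxides, amines, thiols, carboxylic acids, acyl and alkyl halides,
    alkenes) in 3D small-molecule models read from PDB files, and builds
    3D product models of the corresponding click-chemistry reactions by
    template-based rigid-fragment assembly: reactants are fragmented at
    the reacting bond, superimposed onto an idealized product core via
    least-squares tether alignment, relieved of steric clashes by
    discrete dihedral scanning, and merged. Both regioisomers of the
    azide-alkyne Huisgen cycloaddition are generated for non-symmetric
    alkynes. Includes a covalent-radius bond-perception engine, a
    rigid-body geometry toolbox, a combinatorial virtual-library
    enumerator with Lipinski rule-of-five filtering, and a programmatic
    generator of idealized 3D reactant models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
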