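{
  "A1": {
    "name": "Hydropathicity",
    "citation": "Kyte J., Doolittle R.F. (1982) J. Mol. Biol. 157:105-132"
  },
  "A2": {
    "name": "Hydrophobicity (delta G1/2 cal)",
    "citation": "Abraham D.J., Leo A.J. (1987) Proteins 2:130-152"
  },
  "A3": {
    "name": "Hydrophobicity (free energy of transfer to surface in kcal/mole)",
    "citation": "Bull H.B., Breese K. (1974) Arch. Biochem. Biophys. 161:665-670"
  },
  "A4": {
    "name": "Hydrophobicity scale based on the free energy of transfer (kcal/mole)",
    "citation": "Guy H.R. (1985) Biophys. J. 47:61-70"
  },
  "A5": {
    "name": "Hydrophobicity scale (contact energy derived from 3D data)",
    "citation": "Miyazawa S., Jernigan R.L. (1985) Macromolecules 18:534-552"
  },
  "A6": {
    "name": "Hydrophobicity scale (pi-r)",
    "citation": "Roseman M.A. (1988) J. Mol. Biol. 200:513-522"
  },
  "A7": {
    "name": "Hydration potential (kcal/mole) at 25 C",
    "citation": "Wolfenden R. et al. (1981) Biochemistry 20:849-855"
  },
  "A8": {
    "name": "Hydrophilicity",
    "citation": "Hopp T.P., Woods K.R. (1981) Proc. Natl. Acad. Sci. USA 78:3824-3828"
  },
  "A9": {
    "name": "Average surrounding hydrophobicity",
    "citation": "Manavalan P., Ponnuswamy P.K. (1978) Nature 275:673-674"
  },
  "A10": {
    "name": "Hydrophobicity scale (pi-r)",
    "citation": "Fauchere J.-L., Pliska V. (1983) Eur. J. Med. Chem. 18:369-375"
  },
  "A11": {
    "name": "Membrane buried helix parameter",
    "citation": "Rao M.J.K., Argos P. (1986) Biochim. Biophys. Acta 869:197-214"
  },
  "A12": {
    "name": "Antigenicity value X 10",
    "citation": "Welling G.W. et al. (1985) FEBS Lett. 188:215-218"
  },
  "A13": {
    "name": "Hydrophobicity scale (contribution to the stability of globular proteins)",
    "citation": "Nozaki Y., Tanford C. (1971) J. Biol. Chem. 246:2211-2217"
  },
  "A14": {
    "name": "Free energy of transfer from inside to the outside of a globular protein",
    "citation": "Janin J. (1979) Nature 277:491-492"
  },
  "A15": {
    "name": "The proportion of residues 95% buried (in 12 proteins)",
    "citation": "Chothia C. (1976) J. Mol. Biol. 105:1-14"
  },
  "A16": {
    "name": "Mean fractional area loss (f) [average area buried/standard state area]",
    "citation": "Rose G.D. et al. (1985) Science 229:834-838"
  },
  "A17": {
    "name": "Hydrophobicity of physiological L-alpha amino acids",
    "citation": "Black S.D., Mould D.R. (1991) Anal. Biochem. 193:72-82"
  },
  "A18": {
    "name": "Optimized matching hydrophobicity",
    "citation": "Sweet R.M., Eisenberg D. (1983) J. Mol. Biol. 171:479-488"
  },
  "A19": {
    "name": "Normalized consensus hydrophobicity scale",
    "citation": "Eisenberg D. et al. (1984) J. Mol. Biol. 179:125-142"
  },
  "A20": {
    "name": "Average flexibility index",
    "citation": "Bhaskaran R., Ponnuswamy P.K. (1988) Int. J. Pept. Protein Res. 32:241-255"
  },
  "A21": {
    "name": "The atomic weight ratio",
    "citation": "Grantham R. (1974) Science 185:862-864"
  },
  "A22": {
    "name": "Polarity",
    "citation": "Zimmerman J.M. et al. (1968) J. Theor. Biol. 21:170-201"
  },
  "A23": {
    "name": "Molar fraction (%) of 3220 accessible residues",
    "citation": "Janin J. (1979) Nature 277:491-492"
  },
  "A24": {
    "name": "Refractivity",
    "citation": "Jones D.D. (1975) J. Theor. Biol. 50:167-183"
  },
  "A25": {
    "name": "Average area buried on transfer from standard state to folded protein",
    "citation": "Rose G.D. et al. (1985) Science 229:834-838"
  },
  "A26": {
    "name": "Bulkiness",
    "citation": "Zimmerman J.M. et al. (1968) J. Theor. Biol. 21:170-201"
  },
  "A27": {
    "name": "Polarity",
    "citation": "Grantham R. (1974) Science 185:862-864"
  },
  "A28": {
    "name": "Relative mutability of amino acids (Ala = 100)",
    "citation": "Dayhoff M.O. et al. (1978) Atlas of Protein Sequence and Structure 5(Suppl. 3):345-352"
  }
}
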