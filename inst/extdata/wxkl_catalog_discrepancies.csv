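peak_no,issue
2,"printed error -1.9 ppm is inconsistent with the printed formula and detected m/z; C12H22O11 deprotonated recomputes to -0.1 ppm"
10,"detected m/z 718.2728 is inconsistent with the printed formula C49H82O3 (no negative-mode adduct within 20 ppm); printed error is 'None'"
16,"fragment labeled [M-H-Glc]- implies a hexose unit the printed formula C32H24O3 cannot contain"
29,"name 2,2,6-trimethylcyclohexanone corresponds to C9H16O, not the printed formula C9H16O4 (mass arithmetic still verifies against the printed formula)"
35,"printed formula C32H20O has an implausible ring/double-bond count for this retention region; row kept as printed"
36,"printed formula C32H18 contains no oxygen; implausible for an extract constituent, row kept as printed"
58,"notoginsenoside-type name but source column prints DS rather than SQ; recorded as printed"
66,"detected m/z column holds the formate-adduct ion [M-H+FA]- rather than [M-H]-; verifies only under the formate adduct"
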