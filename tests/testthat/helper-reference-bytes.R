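# Reference trajectory fixtures: tiny TRR/XTC files written by an
# independent Gromacs-format implementation, base64-embedded with the exact
# coordinates (nm, float32) they encode. Used to pin the binary layout of
# the readers independently of the package's own writers.

ref_trr_b64 <- "AAAHyQAAAA0AAAAMR01YX3Rybl9maWxlAAAAAAAAAAAAAAAkAAAAAAAAAAAAAAAAAAAAAAAAADwAAAAAAAAAAAAAAAUAAAAAAAAAAAAAAAAAAAAAQAAAAAAAAAAAAAAAAAAAAEAAAAAAAAAAAAAAAAAAAABAAAAAP6AGQj/lr84/xpNWPuactz8Zr2U/36EzPCyIkz/SPAc/zAy+P2+VLD8bJxE/Do3NPwJ+RD9j4Qs/gSoTAAAHyQAAAA0AAAAMR01YX3Rybl9maWxlAAAAAAAAAAAAAAAkAAAAAAAAAAAAAAAAAAAAAAAAADwAAAAAAAAAAAAAAAUAAAABAAAAAEAAAAAAAAAAQAAAAAAAAAAAAAAAAAAAAEAAAAAAAAAAAAAAAAAAAABAAAAAP42yAT/+2Rs/yuvkP59HIz/9LH4+3HniPqQOoD+cz2U9s/yJPZIlfD+Dz8E/brKOP+rLgj+hFPk/g503"

ref_xtc20_b64 <- "AAAHywAAABQAAAADP8AAAEAAAAAAAAAAAAAAAAAAAABAAAAAAAAAAAAAAAAAAAAAQAAAAAAAABREegAAAAABxAAAAAsAAAAjAAAK4AAAC3gAAAtXAAAAIAAAAGImiAAIULUCcx8Iqi7owUStKHD0MkzVIbUXqXmDu4lptVRhRMifhgRloCFAAqe/So1S6JMM5U2Qo6iDtmOe71pnK+0wdWpkBb3DOsDGkhf0u2O2l58mt5CpHYPRSMu/Jq2dXAAA"

# 2 frames x 5 atoms (nm), times 0 and 2 ps, cubic 2 nm box
ref_trr_frame1 <- matrix(c(
    1.2501909732818604, 1.7944276332855225, 1.5513713359832764,
    0.45041438937187195, 0.6003325581550598, 1.747106909751892,
    0.010530608706176281, 1.6424568891525269, 1.5941388607025146,
    0.9358699321746826, 0.6060648560523987, 0.5568512082099915,
    0.5097391605377197, 0.890152633190155, 1.0090965032577515), ncol = 3, byrow = TRUE)
ref_trr_frame2 <- matrix(c(
    1.1069947481155396, 1.9910005331039429, 1.5853238105773926,
    1.2443584203720093, 1.9779202938079834, 0.43061739206314087,
    0.32042407989501953, 1.2250791788101196, 0.08788401633501053,
    0.07136055827140808, 1.0297776460647583, 0.9324120283126831,
    1.8343355655670166, 1.2584525346755981, 1.0282353162765503), ncol = 3, byrow = TRUE)

# 1 frame x 20 atoms (nm), precision 1000
ref_xtc20_frame <- matrix(c(
    1.4906202554702759, 0.7425447702407837, 0.03538207709789276,
    0.5772064328193665, 2.076096296310425, 0.601820170879364,
    1.1086089611053467, 0.011202726513147354, 2.490143299102783,
    0.4633832573890686, 0.8027979135513306, 2.6409964561462402,
    1.5293724536895752, 2.5414507389068604, 1.9191515445709229,
    2.2253129482269287, 0.27448680996894836, 1.6234314441680908,
    1.523316740989685, 2.614018201828003, 1.0837922096252441,
    1.794552206993103, 0.17775492370128632, 1.1628954410552979,
    0.969109058380127, 0.45059919357299805, 2.44901442527771,
    1.138338565826416, 2.9362435340881348, 1.7699750661849976,
    1.8151687383651733, 1.913989782333374, 2.029350757598877,
    0.452364057302475, 1.320940375328064, 0.718691885471344,
    1.207494854927063, 0.29011228680610657, 2.9034841060638428,
    0.6450121402740479, 2.0152955055236816, 0.901260256767273,
    2.6222310066223145, 1.9866442680358887, 0.39484745264053345,
    2.5352230072021484, 2.8348445892333984, 2.7117502689361572,
    1.7091574668884277, 0.4363798499107361, 0.5773904919624329,
    2.783717155456543, 1.6569794416427612, 0.5416575074195862,
    2.6521706581115723, 1.9247151613235474, 1.709082841873169,
    1.1288634538650513, 1.232865810394287, 0.718467652797699), ncol = 3, byrow = TRUE)

decode_b64 <- function(txt) jsonlite::base64_dec(txt)
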