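# Synthetic stand-in for a curated list of 73 commonly used human
# reference (housekeeping) genes, assembled from genes widely cited as
# RT-qPCR normalization controls. Replace with your own curated list
# (one identifier per line, '#' comments allowed) as needed.
ACTB
GAPDH
B2M
YWHAZ
GNAS
OAZ1
PTMA
HPRT1
TBP
UBC
UBB
RPL13A
RPLP0
RPL19
RPL30
RPL27
RPL37A
RPS18
RPS13
RPS29
SDHA
PGK1
PPIA
PPIB
GUSB
TFRC
HMBS
HSP90AB1
HSPA8
EEF1A1
EEF2
TUBB
TUBA1A
ALAS1
POLR2A
YWHAE
CYC1
ATP5F1B
UBE2D2
CANX
CALR
PSMB2
PSMB4
NACA
VCP
TPT1
FAU
RACK1
H3-3A
HNRNPA1
PABPC1
EIF4A2
EIF4G2
MRPL19
PUM1
RPL11
RPL32
RPS11
RPS24
TMBIM6
VPS29
EMC7
CHMP2A
GPI
LDHA
NONO
PGAM1
SNRPD3
ATP5PO
DDX5
ACTG1
MYL6
TMSB4X
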