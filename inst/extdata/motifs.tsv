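name	grammar	fold_class
class1_aspartate	D[DE]xx[DE]	class_I
ddxxd	DDxxD	class_I
ddxxe	DDxxE	class_I
dxdd	DxDD	class_II
dxdtt	DxDTT	class_II
tri5_aspartate	DDS[RI]E	class_I
tri5_triad	NDLFSFYKE	accessory
ddhfd	D[DE]HFD	class_I
ndhfd	NDHFD	accessory
dctae	DC[TI][AS]E	class_II
qw	QW	accessory
nsd	NSD	accessory
dte	DTE	accessory
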