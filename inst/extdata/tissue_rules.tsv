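Rule	eps_hyd	eps_dis	C_perfusion	C_perfusion_neighbour	C_bone	C_bone_neighbour	C_cartilage	d_perfusion	d_bone	d_cartilage	Process
1	Not neg. destructive	About zero	Low	Not low	-	-	-	Increase	-	-	Angiogenesis
2	Not neg. destructive	About zero	Not low	High	-	-	-	Increase	-	-	Angiogenesis
3	Not neg. destructive	Low	Low	Not low	-	-	-	Increase	-	-	Angiogenesis
4	Not neg. destructive	Low	Not low	High	-	-	-	Increase	-	-	Angiogenesis
5	Neg. low	Low	High	-	-	High	Low	-	Increase	-	Intramembranous ossification
6	Pos. low	Low	High	-	-	High	Low	-	Increase	-	Intramembranous ossification
7	Neg. medium	Not destructive	-	-	-	-	-	-	-	Increase	Chondrogenesis
8	Neg. low	Not destructive	-	-	-	-	-	-	-	Increase	Chondrogenesis
9	Neg. medium	Not destructive	-	-	-	Not low	Not low	-	Increase	Decrease	Cartilage calcification
10	Neg. low	Not destructive	-	-	-	Not low	Not low	-	Increase	Decrease	Cartilage calcification
11	About zero	Not destructive	-	-	-	Not low	Not low	-	Increase	Decrease	Cartilage calcification
12	Pos. low	Not destructive	-	-	-	Not low	Not low	-	Increase	Decrease	Cartilage calcification
13	Neg. low	Zero	Not low	-	High	High	Low	-	Increase	Decrease	Endochondral ossification
14	Neg. low	Low	Not low	-	High	High	Low	-	Increase	Decrease	Endochondral ossification
15	Pos. low	Zero	Not low	-	High	High	Low	-	Increase	Decrease	Endochondral ossification
16	Pos. low	Low	Not low	-	High	High	Low	-	Increase	Decrease	Endochondral ossification
17	Neg. destructive	-	-	-	-	-	-	Decrease	Decrease	Decrease	Tissue destruction
18	Pos. destructive	-	-	-	-	-	-	Decrease	Decrease	Decrease	Tissue destruction
19	-	Destructive	-	-	-	-	-	Decrease	Decrease	Decrease	Tissue destruction
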