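country;g1a;g1b;g1c;g2a;g2b;total
Cameroon;204;11;;34;0;257
Côte d'Ivoire;99;11;;15;;127
Djibouti;30;;;10;;46
Egypt;203;30;42;44;;326
Eritrea;4508;218;10;606;107;5449
Ethiopia;2707;143;;528;52;3434
Gambia;432;21;;151;47;654
Ghana;582;133;47;226;62;1050
Guinea;73;29;;17;;127
Iraq;7285;1949;416;3422;146;13218
Kenya;643;120;64;50;17;894
Liberia;310;100;40;74;;526
Nigeria;529;42;;142;27;749
Senegal;71;;;22;;102
Sierra Leone;138;54;37;49;10;288
Somalia;8873;1630;593;3654;206;14956
Sudan;640;78;116;134;;977
Togo;38;;;14;0;62
Uganda;311;124;44;39;16;534
United Republic of Tanzania;340;42;8;36;;432
Yemen;135;;0;38;;186
Other countries;51;;;19;;73
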