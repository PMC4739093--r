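country;g1a;g1b;g1c;g2a;g2b;total
Benin;9;1;0;3;0;13
Burkina Faso;5;2;0;4;0;11
Cameroon;204;11;8;34;0;257
Central African Republic;8;0;0;2;0;10
Chad;7;1;0;3;0;11
Côte d'Ivoire;99;11;1;15;1;127
Djibouti;30;2;1;10;3;46
Egypt;203;30;42;44;7;326
Eritrea;4508;218;10;606;107;5449
Ethiopia;2707;143;4;528;52;3434
Gambia;432;21;3;151;47;654
Ghana;582;133;47;226;62;1050
Guinea;73;29;6;17;2;127
Guinea-Bissau;6;0;0;1;0;7
Iraq;7285;1949;416;3422;146;13218
Kenya;643;120;64;50;17;894
Liberia;310;100;40;74;2;526
Mali;7;2;0;5;0;14
Mauritania;4;0;0;1;0;5
Niger;5;1;0;0;0;6
Nigeria;529;42;9;142;27;749
Senegal;71;5;3;22;1;102
Sierra Leone;138;54;37;49;10;288
Somalia;8873;1630;593;3654;206;14956
Sudan;640;78;116;134;9;977
Togo;38;6;4;14;0;62
Uganda;311;124;44;39;16;534
United Republic of Tanzania;340;42;8;36;6;432
Yemen;135;8;0;38;5;186
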